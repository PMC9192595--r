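#' Read per-molecule two-channel traces
#'
#' Reads the tab-separated trace dialect: a header line
#' \code{molecule_id  frame  donor  acceptor}, frames 1-based and contiguous
#' per molecule. A sidecar file \code{<path>.manifest} with \code{key=value}
#' lines supplies the condition labels; keys starting with a dot are
#' reserved for trace metadata (\code{.frame_interval},
#' \code{.bleach.<molecule_id>}).
#'
#' @param path trace file path.
#' @param manifest optional named list of condition labels, merged over (and
#'   overriding) the sidecar's.
#' @param frameInterval frame duration in seconds used when neither the
#'   sidecar nor the argument provides one.
#' @return a \linkS4class{TraceSet} with molecules in file order.
#' @seealso \code{\link{writeTraces}}
#' @export
readTraces <- function(path, manifest = NULL, frameInterval = 0.1) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = c(molecule_id = "character"),
                           check.names = FALSE)
  need <- c("molecule_id", "frame", "donor", "acceptor")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("trace file format error: missing column(s) ",
         paste(missing, collapse = ", "))
  side <- readManifestSidecar(paste0(path, ".manifest"))
  if (!is.null(side$frame_interval)) frameInterval <- side$frame_interval
  man <- side$manifest
  for (k in names(manifest)) man[[k]] <- manifest[[k]]
  if (length(man) == 0L) man <- list(condition = "unspecified")

  ids <- unique(tab$molecule_id)
  trs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rows <- tab[tab$molecule_id == ids[i], , drop = FALSE]
    rows <- rows[order(rows$frame), , drop = FALSE]
    if (anyDuplicated(rows$frame))
      stop("trace file integrity error: duplicate frame for molecule ",
           ids[i])
    if (!identical(as.integer(rows$frame), seq_len(nrow(rows))))
      stop("trace file integrity error: non-contiguous frames for molecule ",
           ids[i])
    bf <- side$bleach[[ids[i]]]
    trs[[i]] <- new("FretTrace", moleculeId = ids[i],
                    frameInterval = frameInterval,
                    donor = as.numeric(rows$donor),
                    acceptor = as.numeric(rows$acceptor),
                    bleachFrame = if (is.null(bf)) NA_integer_
                                  else as.integer(bf))
  }
  new("TraceSet", traces = trs, manifest = man)
}

readManifestSidecar <- function(path) {
  out <- list(manifest = list(), bleach = list(), frame_interval = NULL)
  if (!file.exists(path)) return(out)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) next
    key <- substr(ln, 1, eq - 1)
    val <- substr(ln, eq + 1, nchar(ln))
    if (key == ".frame_interval") {
      out$frame_interval <- as.numeric(val)
    } else if (startsWith(key, ".bleach.")) {
      out$bleach[[substring(key, 9)]] <- as.integer(val)
    } else if (!startsWith(key, ".")) {
      out$manifest[[key]] <- utils::type.convert(val, as.is = TRUE)
    }
  }
  out
}

#' Write a trace set
#'
#' Emits the tab-separated dialect \code{\link{readTraces}} accepts, plus a
#' \code{<path>.manifest} sidecar carrying the condition labels, the frame
#' interval and any known bleach frames. Intensities are written with 17
#' significant digits so the round trip reproduces every double exactly.
#'
#' @param set a non-empty \linkS4class{TraceSet}.
#' @param path destination file path.
#' @return \code{path}, invisibly.
#' @export
writeTraces <- function(set, path) {
  stopifnot(is(set, "TraceSet"))
  if (length(set@traces) == 0L) stop("cannot write an empty TraceSet")
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines("molecule_id\tframe\tdonor\tacceptor", con)
  for (tr in set@traces) {
    T <- length(tr@donor)
    writeLines(sprintf("%s\t%d\t%.17g\t%.17g", tr@moleculeId, seq_len(T),
                       tr@donor, tr@acceptor), con)
  }
  man <- vapply(set@manifest, function(x) as.character(x)[1], character(1))
  lines <- c(sprintf("%s=%s", names(man), man),
             sprintf(".frame_interval=%.17g",
                     set@traces[[1]]@frameInterval))
  for (tr in set@traces)
    if (!is.na(tr@bleachFrame))
      lines <- c(lines, sprintf(".bleach.%s=%d", tr@moleculeId,
                                tr@bleachFrame))
  writeLines(lines, paste0(path, ".manifest"))
  invisible(path)
}

#' Write simulation ground truth
#'
#' Writes the per-frame state label, docked flag and bleach frame of a
#' simulated set to \code{<path>} as TSV, the format the simulate command
#' emits alongside the traces.
#'
#' @param set a \linkS4class{TraceSet} carrying ground truth.
#' @param path destination file path.
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(set, path) {
  truth <- set@truth
  if (length(truth) == 0L) stop("TraceSet carries no ground truth")
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines("molecule_id\tframe\tstate\tdocked\tbleach_frame", con)
  for (tr in set@traces) {
    id <- tr@moleculeId
    p <- truth$paths[[id]]
    dt <- tr@frameInterval
    T <- length(tr@donor)
    mid <- (seq_len(T) - 0.5) * dt
    seg <- p@segments
    stateAt <- seg$state[findInterval(mid, c(seg$start[1], seg$end),
                                      rightmost.closed = TRUE)]
    bf <- if (is.na(tr@bleachFrame)) "none" else as.character(tr@bleachFrame)
    writeLines(sprintf("%s\t%d\t%s\t%d\t%s", id, seq_len(T), stateAt,
                       as.integer(truth$docked[[id]]), bf), con)
  }
  invisible(path)
}

#' Detect single-step photobleaching
#'
#' Finds the first frame where the running median (window 5) of the total
#' intensity (donor + acceptor) falls below \code{dropFraction} of its
#' initial level (the median of the first ten smoothed frames) and stays
#' below until the end of the trace. Downstream analysis truncates at this
#' index. The detector is invariant under uniform positive rescaling of
#' both channels.
#'
#' @param trace a \linkS4class{FretTrace} with at least two frames.
#' @param dropFraction threshold fraction in (0, 1); default 0.3.
#' @return integer frame index of the collapse, or \code{NA_integer_} when
#'   no bleach step is found.
#' @export
detectBleach <- function(trace, dropFraction = 0.3) {
  stopifnot(is(trace, "FretTrace"))
  if (dropFraction <= 0 || dropFraction >= 1)
    stop("dropFraction must lie strictly between 0 and 1")
  total <- trace@donor + trace@acceptor
  T <- length(total)
  if (T < 2L) stop("bleach detection needs at least two frames")
  k <- min(5L, if (T %% 2L == 1L) T else T - 1L)
  sm <- if (k >= 3L) stats::runmed(total, k) else total
  thr <- dropFraction * stats::median(sm[seq_len(min(10L, T))])
  below <- sm < thr
  # first index from which the trace stays below the threshold
  stays <- rev(cumprod(rev(below))) > 0
  if (!any(stays)) return(NA_integer_)
  which(stays)[1L]
}
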