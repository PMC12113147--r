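#' Read a 1D reduced SAXS curve from a plain-text file
#'
#' Parses the common 3-column reduced-SAXS text dialect: whitespace- or
#' comma-delimited columns (q, I, optional error), `#`-prefixed comment
#' lines and non-numeric header lines skipped. `# key: value` comment lines
#' are parsed into the curve metadata. Rows with q <= 0 or non-finite
#' intensity are dropped (the count is reported via a message). With
#' `unit = "angstrom"` the q column is converted from inverse Angstrom to
#' inverse nm (factor 10).
#'
#' @param path file path.
#' @param unit q unit in the file: `"nm"` (default, nm^-1) or `"angstrom"`.
#' @return a [saxs_curve()].
#' @export
read_curve <- function(path, unit = c("nm", "angstrom")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  metadata <- list()
  rows <- list()
  dropped <- 0L
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
      if (length(m) == 3) metadata[[trimws(m[2])]] <- trimws(m[3])
      next
    }
    parts <- strsplit(ln, "[,[:space:]]+")[[1]]
    parts <- parts[nzchar(parts)]
    vals <- suppressWarnings(as.numeric(parts))
    if (anyNA(vals)) next  # non-numeric header line
    if (length(vals) < 2) stop("format error: fewer than 2 columns in ", path)
    if (vals[1] <= 0 || !is.finite(vals[2])) {
      dropped <- dropped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- vals[1:min(3, length(vals))]
  }
  if (length(rows) < 2) stop("malformed file (fewer than 2 valid rows): ", path)
  ncol <- min(vapply(rows, length, integer(1)))
  m <- do.call(rbind, lapply(rows, function(r) r[1:ncol]))
  if (dropped > 0) message(dropped, " invalid row(s) dropped from ", path)
  q <- m[, 1]
  if (unit == "angstrom") q <- q * 10
  unc <- if (ncol >= 3 && all(is.finite(m[, 3])) && all(m[, 3] > 0)) {
    m[, 3]
  } else {
    NULL
  }
  saxs_curve(q, pmax(m[, 2], 0), uncertainty = unc, metadata = metadata)
}

#' Write a curve as a 3-column plain-text file
#'
#' Metadata tags are written as `# key: value` header lines, followed by
#' q / intensity / (optional) uncertainty columns at 9 significant digits.
#' Deterministic formatting; [read_curve()] round-trips the result.
#'
#' @param curve a [saxs_curve()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "saxs_curve"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(curve$metadata)) {
    writeLines(sprintf("# %s: %s", nm, format(curve$metadata[[nm]])), con)
  }
  writeLines(sprintf("# columns: q_nm^-1 intensity%s",
                     if (is.null(curve$uncertainty)) "" else " uncertainty"),
             con)
  fmt <- function(x) formatC(x, digits = 9, format = "g")
  if (is.null(curve$uncertainty)) {
    writeLines(paste(fmt(curve$q), fmt(curve$intensity)), con)
  } else {
    writeLines(paste(fmt(curve$q), fmt(curve$intensity),
                     fmt(curve$uncertainty)), con)
  }
  invisible(path)
}

#' Pairwise frame similarity matrix
#'
#' Quality control for repeated short exposures of one sample (radiation
#' damage screening): entry (i, j) is the Pearson correlation of
#' `log10(pmax(I, floor))` between frames i and j, where `floor` is the
#' smallest positive intensity across all frames times 1e-3. Frames must
#' share an identical q grid; no interpolation is performed.
#'
#' @param frames list of [saxs_curve()] objects on one shared grid (>= 2).
#' @return object of class `frame_set`: the `frames` plus the symmetric
#'   `similarity` matrix with unit diagonal.
#' @export
similarity_matrix <- function(frames) {
  stopifnot(is.list(frames), length(frames) >= 2,
            all(vapply(frames, inherits, logical(1), "saxs_curve")))
  q0 <- frames[[1]]$q
  same <- vapply(frames, function(f) {
    length(f$q) == length(q0) && all(f$q == q0)
  }, logical(1))
  if (!all(same)) stop("mismatched q grids; frames must share one grid")
  pos <- unlist(lapply(frames, function(f) f$intensity[f$intensity > 0]))
  if (length(pos) == 0) stop("all frames are non-positive everywhere")
  floor_ <- min(pos) * 1e-3
  logI <- vapply(frames, function(f) log10(pmax(f$intensity, floor_)),
                 numeric(length(q0)))
  if (any(apply(logI, 2, stats::sd) == 0)) {
    stop("constant (degenerate) frame; similarity undefined")
  }
  sim <- stats::cor(logI)
  diag(sim) <- 1
  dimnames(sim) <- NULL
  structure(list(frames = frames, similarity = sim), class = "frame_set")
}

#' Average consistent frames
#'
#' Excludes frames judged inconsistent with the ensemble and averages the
#' rest pointwise. A frame is excluded when its mean off-diagonal
#' log-correlation falls below `threshold`, or when its median intensity
#' over the ensemble-median frame falls outside `[0.5, 2]` (log-correlation
#' is blind to pure rescaling, so a scaled outlier needs this supplementary
#' check). The averaged curve's uncertainty is the per-point standard error
#' of the mean across retained frames, or the propagated reported errors
#' when every retained frame carries them and only one frame remains.
#'
#' @param fs a `frame_set` from [similarity_matrix()].
#' @param threshold mean off-diagonal similarity cutoff (default 0.99).
#' @param scale_band allowed frame-median / ensemble-median ratio range.
#' @return a [saxs_curve()]; metadata records the retained / excluded frame
#'   indices.
#' @export
average_frames <- function(fs, threshold = 0.99, scale_band = c(0.5, 2)) {
  stopifnot(inherits(fs, "frame_set"))
  frames <- fs$frames
  sim <- fs$similarity
  n <- length(frames)
  mean_off <- (rowSums(sim) - diag(sim)) / (n - 1)
  med_frame <- apply(vapply(frames, `[[`, numeric(length(frames[[1]]$q)),
                            "intensity"), 1, stats::median)
  med_frame_pos <- stats::median(med_frame[med_frame > 0])
  scale_ratio <- vapply(frames, function(f) {
    stats::median(f$intensity) / med_frame_pos
  }, numeric(1))
  keep <- mean_off >= threshold &
    scale_ratio >= scale_band[1] & scale_ratio <= scale_band[2]
  if (!any(keep)) stop("all frames excluded at threshold ", threshold)
  if (any(!keep)) {
    message("excluded frame(s): ", paste(which(!keep), collapse = ", "))
  }
  kept <- frames[keep]
  m <- vapply(kept, `[[`, numeric(length(kept[[1]]$q)), "intensity")
  m <- matrix(m, ncol = length(kept))
  avg <- rowMeans(m)
  all_have_err <- all(vapply(kept, function(f) !is.null(f$uncertainty),
                             logical(1)))
  if (all_have_err) {
    e2 <- vapply(kept, function(f) f$uncertainty^2, numeric(nrow(m)))
    sem <- sqrt(rowSums(matrix(e2, ncol = length(kept)))) / length(kept)
  } else if (length(kept) > 1) {
    sem <- apply(m, 1, stats::sd) / sqrt(length(kept))
  } else {
    sem <- rep(0, nrow(m))
  }
  unc <- if (all(sem > 0)) sem else NULL
  saxs_curve(frames[[1]]$q, avg, uncertainty = unc,
             metadata = list(n_frames = length(kept),
                             excluded = paste(which(!keep), collapse = ",")))
}
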