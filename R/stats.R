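#' Band-averaged DTF value for one direction
#'
#' Arithmetic mean of `values[i, j, ]` (flow `j -> i`) over the grid
#' frequencies lying in `[band[1], band[2]]`, both ends inclusive.
#'
#' @param dtf a `dtf_spectrum`.
#' @param band numeric length-2, `c(f_lo, f_hi)` in Hz.
#' @param direction length-2: source then target, as channel indices or
#'   labels, i.e. `c(j, i)` for the flow `j -> i`.
#' @return Scalar band-averaged DTF.
#' @export
band_average_dtf <- function(dtf, band = c(3, 40), direction) {
  stopifnot(inherits(dtf, "dtf_spectrum"), length(band) == 2L)
  if (band[1L] >= band[2L]) stop("band must satisfy f_lo < f_hi")
  sel <- dtf$freqs >= band[1L] & dtf$freqs <= band[2L]
  if (!any(sel))
    stop("no grid frequencies inside band [", band[1L], ", ", band[2L], "] Hz")
  dir <- resolve_direction(direction, dtf$labels)
  mean(dtf$values[dir[2L], dir[1L], sel])
}

resolve_direction <- function(direction, labels) {
  if (is.character(direction)) {
    idx <- match(direction, labels)
    if (anyNA(idx)) stop("unknown channel label in direction: ",
                         paste(direction[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(direction)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test of equal distributions. Uses exact enumeration when the
#' combined sample size is at most 12 and the data are tie-free, otherwise
#' the normal approximation with tie correction and continuity correction.
#'
#' @param xs,ys numeric samples (non-empty).
#' @return List with `statistic` (the Mann-Whitney U of `xs`) and
#'   `p_value`.
#' @export
ranksum_test <- function(xs, ys) {
  if (length(xs) < 1L || length(ys) < 1L) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(xs, ys)) > 0L
  use_exact <- (length(xs) + length(ys) <= 12L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(xs, ys, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1) via
#' [stats::p.adjust()], with rejection flags at level `q`.
#'
#' @param p_raw vector of raw p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return List with `p_adjusted` and logical `reject`.
#' @export
fdr_bh <- function(p_raw, q = 0.05) {
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p_raw, method = "BH")
  list(p_adjusted = adj, reject = adj <= q)
}

#' Condition contrasts of band-averaged DTFs
#'
#' For every requested direction (and modality, when several are supplied)
#' computes per-segment band-averaged DTF values in each condition,
#' tests wakefulness vs anaesthesia with the rank-sum test, and applies
#' Benjamini-Hochberg FDR jointly across all contrasts in the call. The
#' effect sign is `median(A) - median(W)` (negative = decrease under
#' anaesthesia).
#'
#' @param dtf_w,dtf_a per-segment DTF spectra for conditions W and A:
#'   either a plain list of `dtf_spectrum` (one modality) or a named list
#'   of such lists, one entry per modality.
#' @param band frequency band in Hz (default `c(3, 40)`).
#' @param directions list of length-2 vectors `c(source, target)`; default
#'   both cross-directions of a two-channel system.
#' @param q FDR level (default 0.05).
#' @return A data.frame with one row per contrast: `modality`, `from`,
#'   `to`, `statistic`, `p_raw`, `p_fdr`, `significant`, `median_w`,
#'   `median_a`, `effect` (median_a - median_w). Per-segment values are
#'   attached as `attr(, "values")`; the FDR family size as
#'   `attr(, "family_size")`.
#' @export
compare_conditions <- function(dtf_w, dtf_a, band = c(3, 40),
                               directions = NULL, q = 0.05) {
  as_modal <- function(x, nm) {
    if (length(x) && inherits(x[[1L]], "dtf_spectrum"))
      stats::setNames(list(x), nm)
    else x
  }
  dtf_w <- as_modal(dtf_w, "M1")
  dtf_a <- as_modal(dtf_a, "M1")
  if (!identical(names(dtf_w), names(dtf_a)))
    stop("condition W and A must provide the same modalities")
  rows <- list()
  values <- list()
  for (mod in names(dtf_w)) {
    w <- dtf_w[[mod]]; a <- dtf_a[[mod]]
    if (length(w) != length(a))
      stop("segment counts differ between conditions for modality ", mod,
           " (", length(w), " vs ", length(a), ")")
    labels <- w[[1L]]$labels
    dirs <- directions
    if (is.null(dirs)) {
      if (length(labels) != 2L)
        stop("directions must be given explicitly for k != 2 channels")
      dirs <- list(c(labels[1L], labels[2L]), c(labels[2L], labels[1L]))
    }
    for (d in dirs) {
      vw <- vapply(w, band_average_dtf, numeric(1L), band = band, direction = d)
      va <- vapply(a, band_average_dtf, numeric(1L), band = band, direction = d)
      rt <- ranksum_test(vw, va)
      dn <- if (is.character(d)) d else labels[as.integer(d)]
      key <- paste(mod, dn[1L], dn[2L], sep = ".")
      rows[[key]] <- data.frame(
        modality = mod, from = dn[1L], to = dn[2L],
        statistic = rt$statistic, p_raw = rt$p_value,
        median_w = stats::median(vw), median_a = stats::median(va),
        effect = stats::median(va) - stats::median(vw),
        stringsAsFactors = FALSE)
      values[[key]] <- list(values_w = vw, values_a = va)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  fdr <- fdr_bh(out$p_raw, q)
  out$p_fdr <- fdr$p_adjusted
  out$significant <- fdr$reject
  attr(out, "values") <- values
  attr(out, "family_size") <- nrow(out)
  attr(out, "q") <- q
  attr(out, "band") <- band
  out
}
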