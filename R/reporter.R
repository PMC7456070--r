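#' Dual-luciferase frameshift readout
#'
#' Each replicate's firefly luminescence is normalized to its own Renilla
#' internal control (per-replicate normalization, the standard
#' dual-luciferase practice); the readout is the ratio of condition means,
#' `mean(firefly/renilla | test) / mean(firefly/renilla | control)`.
#' Because a -1 slip between the two reporters puts firefly out of frame
#' behind a premature stop, a lower readout means more frameshifting.
#'
#' @param pairs data.frame with columns `firefly` (>= 0), `renilla` (> 0)
#'   and `condition`.
#' @param test,control condition labels to compare.
#' @param per_replicate normalize per replicate (default) or per condition
#'   (sum of firefly over sum of renilla).
#' @return unitless relative firefly activity.
#' @examples
#' df <- data.frame(firefly = c(50, 100), renilla = c(100, 100),
#'                  condition = c("ko", "wt"))
#' luciferase_readout(df, test = "ko", control = "wt")  # 0.5
#' @export
luciferase_readout <- function(pairs, test, control, per_replicate = TRUE) {
  need <- c("firefly", "renilla", "condition")
  if (!all(need %in% names(pairs)))
    stop(sprintf("pairs must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  if (any(pairs$renilla <= 0))
    stop("renilla luminescence must be positive", call. = FALSE)
  if (any(pairs$firefly < 0))
    stop("firefly luminescence must be non-negative", call. = FALSE)
  for (cond in c(test, control))
    if (!any(pairs$condition == cond))
      stop(sprintf("missing condition '%s'", cond), call. = FALSE)
  grp <- function(cond) pairs[pairs$condition == cond, , drop = FALSE]
  activity <- function(g) {
    if (per_replicate) mean(g$firefly / g$renilla)
    else sum(g$firefly) / sum(g$renilla)
  }
  activity(grp(test)) / activity(grp(control))
}

#' Dual-GST frameshift percentage
#'
#' The -1 PRF percentage from a dual-GST reporter blot: the intensity of
#' the dual-GST band (the frameshift product, upper band) over the sum of
#' the dual-GST and single-GST band intensities, times 100. Vectorized over
#' replicates; scale-invariant in the band intensities.
#'
#' @param dual_intensity intensity of the dual-GST (frameshift) band, >= 0.
#' @param single_intensity intensity of the single-GST band, >= 0.
#' @return percentage in \[0, 100\].
#' @examples
#' gst_prf_percent(1, 3)  # 25
#' @export
gst_prf_percent <- function(dual_intensity, single_intensity) {
  if (any(dual_intensity < 0) || any(single_intensity < 0))
    stop("band intensities must be non-negative", call. = FALSE)
  tot <- dual_intensity + single_intensity
  if (any(tot == 0))
    stop("both band intensities are zero", call. = FALSE)
  100 * dual_intensity / tot
}

#' Unpaired two-tailed Student's t test between replicate groups
#'
#' Classical pooled-variance two-sample t with `n_x + n_y - 2` degrees of
#' freedom (not Welch's).
#'
#' @param x,y numeric replicate values, each of length >= 2.
#' @return list with `t`, `p` (two-sided) and `df`.
#' @examples
#' compare_two_groups(c(1, 2), c(3, 4))
#' @export
compare_two_groups <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("zero pooled variance", call. = FALSE)
  fit <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter))
}
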