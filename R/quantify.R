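#' Poisson rate and confidence interval from droplet counts
#'
#' The standard digital-PCR estimator: with droplets loaded at mean rate
#' `lambda` copies/droplet, the fraction of negative droplets estimates
#' `exp(-lambda)`, so `lambda = -log(n_neg / n_total)`. The 95% CI uses the
#' delta-method standard error of the log negative fraction,
#' `SE = sqrt((n_total - n_neg) / (n_total * n_neg))`, with a normal
#' interval truncated at zero.
#'
#' @param n_neg Number of droplets negative for the species of interest
#'   (`0 < n_neg <= n_total`; `n_neg = 0` is a saturated well and raises an
#'   error, since the rate is unbounded).
#' @param n_total Total droplets considered.
#' @param conf Confidence level (default 0.95).
#' @return A list with `lambda`, `se`, `ci_low`, `ci_high`, `n_neg`,
#'   `n_total`.
#' @examples
#' poisson_lambda(3679, 10000)$lambda  # ~1.000
#' @export
poisson_lambda <- function(n_neg, n_total, conf = 0.95) {
  n_neg <- assert_count(n_neg, "n_neg")
  n_total <- assert_count(n_total, "n_total", minimum = 1)
  assert_scalar_number(conf, "conf", lower = 0.5, upper = 0.999999)
  if (n_neg > n_total) stop("n_neg cannot exceed n_total")
  if (n_neg == 0L)
    stop("saturated: no negative droplets, rate unbounded; dilute the input")
  lambda <- -log(n_neg / n_total)
  se <- sqrt((n_total - n_neg) / (as.numeric(n_total) * n_neg))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(lambda = lambda, se = se,
       ci_low = max(0, lambda - z * se),
       ci_high = lambda + z * se,
       n_neg = n_neg, n_total = n_total)
}

#' Quantify WT, HDR and NHEJ from gated cluster counts
#'
#' Because some droplet populations cannot be separated (WT and NHEJ+WT
#' droplets share the WT+ cluster; HDR and HDR+WT droplets share the HDR+
#' cluster), each class is estimated on an appropriate droplet subset:
#' \describe{
#'   \item{NHEJ}{`n_neg = n_empty`, `n_total = n_empty + n_nhej` (the
#'     NHEJ single-positive and empty droplets).}
#'   \item{HDR}{`n_neg = n_empty + n_nhej + n_wt_plus`, `n_total` = all four
#'     clusters.}
#'   \item{WT}{`n_neg = n_empty + n_nhej`,
#'     `n_total = n_empty + n_nhej + n_wt_plus`.}
#' }
#' Each subset behaves as an independent Poisson experiment for its class,
#' so [poisson_lambda()] applies unchanged. Allelic frequencies are the
#' class rates normalized to 100%. Copies are reported as `lambda` times
#' the total droplets analyzed (all four clusters); concentration divides
#' the rate by the droplet volume.
#'
#' @param counts A [cluster_counts()] with `n_empty > 0`.
#' @param droplet_volume_nl Droplet volume in nanolitres (default 0.85).
#' @param conf Confidence level for the per-class CIs.
#' @return An object of class `quant_estimate`: named numeric vectors
#'   (`wt`, `hdr`, `nhej`) `lambda`, `se`, `ci_low`, `ci_high`, `copies`,
#'   `concentration` (copies/µl) and `frequency` (percent of total copies;
#'   `NA` when no template was detected), plus the counts and droplet
#'   totals used.
#' @examples
#' q <- quantify_classes(cluster_counts(9000, 0, 1000, 0))
#' q$lambda["wt"]  # log(10000/9000)
#' @export
quantify_classes <- function(counts, droplet_volume_nl = 0.85, conf = 0.95) {
  stopifnot(inherits(counts, "cluster_counts"))
  e <- counts$n_empty; nn <- counts$n_nhej
  w <- counts$n_wt_plus; h <- counts$n_hdr_plus
  n_all <- e + nn + w + h
  if (n_all == 0L) stop("no droplets in the four quantification clusters")
  if (e == 0L)
    stop("saturated well: no empty droplets; rates are unbounded")
  est <- list(wt   = poisson_lambda(e + nn, e + nn + w, conf),
              hdr  = poisson_lambda(e + nn + w, n_all, conf),
              nhej = poisson_lambda(e, e + nn, conf))
  pick <- function(f) vapply(est, `[[`, numeric(1), f)
  lambda <- pick("lambda")
  total <- sum(lambda)
  frequency <- if (total > 0) 100 * lambda / total
               else stats::setNames(rep(NA_real_, 3L), names(lambda))
  structure(list(lambda = lambda, se = pick("se"),
                 ci_low = pick("ci_low"), ci_high = pick("ci_high"),
                 copies = lambda * n_all,
                 concentration = lambda_to_concentration(lambda,
                                                         droplet_volume_nl),
                 frequency = frequency,
                 n_droplets = n_all, counts = counts,
                 droplet_volume_nl = droplet_volume_nl, conf = conf,
                 no_template = total == 0),
            class = "quant_estimate")
}

#' @export
print.quant_estimate <- function(x, digits = 1, ...) {
  cat(sprintf("ddPCR quantification (%d droplets, %g nL/droplet):\n",
              x$n_droplets, x$droplet_volume_nl))
  df <- as.data.frame(x)
  df$lambda <- signif(df$lambda, 4)
  df$ci_low <- signif(df$ci_low, 4)
  df$ci_high <- signif(df$ci_high, 4)
  df$copies <- round(df$copies)
  df$concentration <- signif(df$concentration, 4)
  df$frequency <- round(df$frequency, digits)
  print(df, row.names = FALSE)
  if (isTRUE(x$no_template))
    cat("note: no template detected; frequencies undefined\n")
  invisible(x)
}

#' @export
as.data.frame.quant_estimate <- function(x, ...) {
  data.frame(class = c("wt", "hdr", "nhej"),
             lambda = unname(x$lambda), se = unname(x$se),
             ci_low = unname(x$ci_low), ci_high = unname(x$ci_high),
             copies = unname(x$copies),
             concentration = unname(x$concentration),
             frequency = unname(x$frequency))
}

#' Allelic frequencies from copy numbers
#'
#' @param copies_hdr,copies_nhej,copies_wt Non-negative copy numbers; at
#'   least one must be positive.
#' @return Named numeric vector of percentages (`hdr`, `nhej`, `wt`)
#'   summing to 100; round for display (the field reports one decimal).
#' @examples
#' round(frequencies_from_copies(79, 677, 11971), 1)  # HDR 0.6, NHEJ 5.3
#' @export
frequencies_from_copies <- function(copies_hdr, copies_nhej, copies_wt) {
  for (v in list(copies_hdr, copies_nhej, copies_wt))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("copy numbers must be single non-negative numbers")
  total <- copies_hdr + copies_nhej + copies_wt
  if (total <= 0) stop("at least one copy number must be positive")
  c(hdr = 100 * copies_hdr / total,
    nhej = 100 * copies_nhej / total,
    wt = 100 * copies_wt / total)
}

#' Merge replicate wells by pooling cluster counts
#'
#' Element-wise sum of cluster counts across wells; merging wells before
#' quantification is how replicate wells of the same sample are combined
#' (rates are invariant to pooling identical wells, while CIs tighten).
#'
#' @param ... [cluster_counts()] objects, [assign_clusters()] results, or a
#'   single list of either.
#' @return A [cluster_counts()].
#' @export
merge_wells <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) &&
      !inherits(xs[[1]], c("cluster_counts", "gated_well")))
    xs <- xs[[1]]
  if (length(xs) == 0L) stop("no wells to merge")
  xs <- lapply(xs, function(x) {
    if (inherits(x, "gated_well")) x$counts
    else if (inherits(x, "cluster_counts")) x
    else stop("merge_wells accepts cluster_counts or gated_well objects")
  })
  sum_of <- function(f) sum(vapply(xs, `[[`, numeric(1), f))
  cluster_counts(sum_of("n_empty"), sum_of("n_nhej"), sum_of("n_wt_plus"),
                 sum_of("n_hdr_plus"), sum_of("n_anomalous"))
}

#' Subtract the assay background measured on unedited DNA
#'
#' Background signal measured on an equivalent amount of unedited WT
#' genomic DNA is subtracted from the edited sample's frequency; negative
#' corrected frequencies are clamped to zero (reported as undetectable).
#'
#' @param edited,control Frequencies in percent (`>= 0`); vectorized.
#' @return `pmax(0, edited - control)`.
#' @export
subtract_background <- function(edited, control) {
  if (any(!is.finite(edited)) || any(edited < 0) ||
      any(!is.finite(control)) || any(control < 0))
    stop("frequencies must be finite and >= 0")
  pmax(0, edited - control)
}
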