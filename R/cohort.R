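# Scalar muscle-quality metrics and pre/post cohort comparison with
# two-tailed heteroscedastic (Welch) t-tests; differences flagged at
# p < 0.05 per comparison, with no multiplicity correction by default.

#' Mean HU value
#'
#' The conventional whole-volume muscle-quality metric: the arithmetic
#' mean of voxel HU values. For a pre-binned histogram the count-weighted
#' mean of bin centers is returned, which approximates the voxel mean to
#' within half a bin width.
#'
#' @param x numeric vector of HU values, or an `hu_histogram`.
#' @return mean HU (scalar).
#' @export
mean_hu <- function(x) {
  if (inherits(x, "hu_histogram")) {
    if (x$n_total == 0) stop("histogram has zero total count", call. = FALSE)
    return(sum(hu_bin_centers() * x$counts) / x$n_total)
  }
  x <- as.numeric(x)
  if (length(x) == 0) stop("empty input", call. = FALSE)
  mean(x)
}

#' Welch's unequal-variance t-test
#'
#' Two-tailed two-sample t-test without the equal-variance assumption,
#' with Welch-Satterthwaite degrees of freedom.
#'
#' @param a,b numeric sample vectors, each of length `>= 2`; at least one
#'   must have nonzero variance.
#' @return list with elements `t` (statistic, computed as `a` minus `b`),
#'   `df` (Welch-Satterthwaite degrees of freedom) and `p` (two-tailed).
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample must have at least 2 observations", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b))
    return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

# the 11 fitted parameter columns (deferred: fitting.R loads later)
cohort_param_cols <- function() FREE_PARAM_NAMES

#' Assemble a cohort table from fitted histograms
#'
#' Reads a manifest (columns `subject_id`, `leg`, `timepoint`, `path`,
#' each path a pre-binned histogram CSV), fits the trimodal model to each
#' entry, and returns one row per (subject, leg, timepoint) with the 11
#' fitted parameters, R^2, mean HU and the three tissue count fractions.
#'
#' @param manifest data frame or path to a manifest CSV.
#' @param ... passed to [fit_trimodal].
#' @return a `data.frame` cohort table.
#' @export
build_cohort_table <- function(manifest, ...) {
  if (is.character(manifest)) {
    if (!file.exists(manifest))
      stop("file not found: ", manifest, call. = FALSE)
    manifest <- utils::read.csv(manifest)
  }
  req <- c("subject_id", "leg", "timepoint", "path")
  if (!all(req %in% names(manifest)))
    stop("manifest must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  key <- interaction(manifest$subject_id, manifest$leg, manifest$timepoint)
  if (anyDuplicated(key))
    stop("duplicate (subject_id, leg, timepoint) keys in manifest",
         call. = FALSE)
  tissue <- bin_tissue()
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    h <- read_histogram_csv(manifest$path[i])
    fit <- fit_trimodal(h, ...)
    fracs <- tapply(h$counts, tissue, sum) / h$n_total
    cbind(
      data.frame(subject_id = manifest$subject_id[i], leg = manifest$leg[i],
                 timepoint = manifest$timepoint[i]),
      as.data.frame(as.list(tp_to_free(fit$params))),
      data.frame(r_squared = fit$r_squared, mean_hu = mean_hu(h),
                 frac_fat = fracs[["fat"]],
                 frac_connective = fracs[["connective"]],
                 frac_muscle = fracs[["muscle"]])
    )
  })
  do.call(rbind, rows)
}

#' Pre- versus post-surgery cohort comparison
#'
#' For each leg and each of the 11 fitted model parameters, compares the
#' pre and post groups across subjects with [welch_t_test] and flags
#' p < 0.05. Tests are unpaired (heteroscedastic) even though pre and
#' post come from the same subjects. Subjects missing either timepoint
#' for a leg are excluded from that leg's comparison with a warning. No
#' multiple-testing correction is applied by default; the number of
#' comparisons is printed so users can judge, and `bonferroni = TRUE`
#' divides the significance threshold by that number.
#'
#' @param table cohort table as from [build_cohort_table]: one row per
#'   (subject_id, leg, timepoint) with the 11 parameter columns.
#' @param alpha significance level (default 0.05).
#' @param bonferroni apply Bonferroni correction to `alpha`.
#' @return `data.frame` with columns `parameter`, `tissue`, `leg`,
#'   `mean_pre`, `mean_post`, `t`, `df`, `p`, `significant`.
#' @export
compare_cohort <- function(table, alpha = 0.05, bonferroni = FALSE) {
  req <- c("subject_id", "leg", "timepoint", cohort_param_cols())
  if (!all(req %in% names(table)))
    stop("cohort table lacks columns: ",
         paste(setdiff(req, names(table)), collapse = ", "), call. = FALSE)
  if (!all(table$timepoint %in% c("pre", "post")))
    stop("timepoint must be 'pre' or 'post'", call. = FALSE)
  legs <- unique(as.character(table$leg))
  out <- list()
  n_comparisons <- length(legs) * length(cohort_param_cols())
  thr <- if (bonferroni) alpha / n_comparisons else alpha
  for (leg in legs) {
    sub <- table[table$leg == leg, ]
    pre <- sub[sub$timepoint == "pre", ]
    post <- sub[sub$timepoint == "post", ]
    complete <- intersect(pre$subject_id, post$subject_id)
    dropped <- setdiff(unique(sub$subject_id), complete)
    if (length(dropped))
      warning("leg '", leg, "': excluding subjects missing a timepoint: ",
              paste(dropped, collapse = ", "))
    pre <- pre[pre$subject_id %in% complete, ]
    post <- post[post$subject_id %in% complete, ]
    if (length(complete) < 2)
      stop("leg '", leg, "': need at least 2 subjects with both timepoints",
           call. = FALSE)
    for (col in cohort_param_cols()) {
      ht <- welch_t_test(pre[[col]], post[[col]])
      out[[length(out) + 1L]] <- data.frame(
        parameter = sub("^[a-z]+_", "", col),
        tissue = sub("_.*$", "", col),
        leg = leg,
        mean_pre = mean(pre[[col]]), mean_post = mean(post[[col]]),
        t = ht$t, df = ht$df, p = ht$p,
        significant = ht$p < thr
      )
    }
  }
  res <- do.call(rbind, out)
  message(n_comparisons, " comparisons at alpha = ", format(thr),
          if (bonferroni) " (Bonferroni-corrected)" else
            " (no multiplicity correction)")
  res
}
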