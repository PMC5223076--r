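# Shared fixtures: parameter sets and small helpers used across tests.

# well-separated trimodal truth for recovery experiments
make_truth <- function() {
  trimodal_params(
    fat        = component_params(N = 5e5,   mu = -80, sigma = 22, alpha = -1.2),
    connective = component_params(N = 1.5e5, mu = 5,   sigma = 30, alpha = 0),
    muscle     = component_params(N = 1e6,   mu = 55,  sigma = 13, alpha = 1.8)
  )
}

# a single-component model (the other two amplitudes at zero)
make_single <- function(tissue, N, mu, sigma, alpha = 0) {
  base <- list(fat = c(-80, 20), connective = c(5, 25), muscle = c(55, 15))
  comps <- lapply(names(base), function(t) {
    if (t == tissue) component_params(N, mu, sigma,
                                      if (t == "connective") 0 else alpha)
    else component_params(0, base[[t]][1], base[[t]][2], 0)
  })
  names(comps) <- names(base)
  trimodal_params(fat = comps$fat, connective = comps$connective,
                  muscle = comps$muscle)
}

# expected fitted N for each component when n voxels are drawn from tp and
# density-at-centers is regressed on counts (N carries a bin-width scale)
expected_fitted_N <- function(tp, n) {
  w <- vapply(tp[c("fat", "connective", "muscle")], function(p) p$N,
              numeric(1))
  n * (w / sum(w)) * 3.125
}

# straight vertical fat|muscle interface image: `left` fat columns then
# muscle columns, constant HU per tissue
make_interface_image <- function(nrow = 10, ncol = 10, left = 5,
                                 fat_hu = -80, muscle_hu = 55) {
  hu <- matrix(muscle_hu, nrow, ncol)
  hu[, seq_len(left)] <- fat_hu
  hu
}

# cohort table of 11 parameter columns drawn N(mean, sd) per cell
make_cohort_table <- function(n_subjects, legs = "operative",
                              shift = numeric(0)) {
  cols <- trimodr:::FREE_PARAM_NAMES
  rows <- list()
  for (leg in legs) for (tpnt in c("pre", "post")) {
    m <- matrix(rnorm(n_subjects * length(cols)), n_subjects,
                dimnames = list(NULL, cols))
    for (col in names(shift))
      if (tpnt == "post") m[, col] <- m[, col] + shift[[col]]
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(subject_id = paste0("S", seq_len(n_subjects)), leg = leg,
                 timepoint = tpnt),
      as.data.frame(m))
  }
  do.call(rbind, rows)
}
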