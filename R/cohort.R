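#' Generate a cohort of muscle parameter sets
#'
#' Draws `n` per-muscle parameter sets around the committed group defaults.
#' Inter-muscle variability is multiplicative lognormal with mean exactly 1
#' (`meanlog = -sigma^2/2`), applied independently to each parameter:
#' slow-response gains and the force scale use `cv_inter_muscle`, time and
#' rate constants use `cv_kinetics`. Group means of the parameters therefore
#' equal the group defaults up to Monte-Carlo error, and the coefficient of
#' variation of each perturbed parameter equals the nominal CV exactly in
#' distribution.
#'
#' @param group `"CONT"` or `"MCT"`, or a [muscle_params()] object to use as
#'   the cohort center.
#' @param n Number of muscles (>= 1).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return List of `n` [muscle_params()] objects (with `$muscle_id` set).
#' @export
make_cohort <- function(group, n, seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)
  base <- if (inherits(group, "muscle_params")) group else default_params(group)

  gain_fields <- c("sfr_gain_ca", "sfr_gain_sens", "sfr_dia_gain",
                   "prp_load_gain", "f_ref")
  kin_fields <- c("tau_ca_rise", "tau_ca_decay", "k_act", "k_rel")

  draw <- function(cv, k) {
    if (cv <= 0) return(matrix(1, nrow = n, ncol = k))
    s <- sqrt(log(1 + cv^2))
    matrix(rlnorm(n * k, meanlog = -s^2 / 2, sdlog = s), nrow = n)
  }
  mult <- with_seed(seed, list(
    gain = draw(base$cv_inter_muscle, length(gain_fields)),
    kin = draw(base$cv_kinetics, length(kin_fields))
  ))

  lapply(seq_len(n), function(i) {
    p <- base
    for (j in seq_along(gain_fields)) {
      p[[gain_fields[j]]] <- p[[gain_fields[j]]] * mult$gain[i, j]
    }
    for (j in seq_along(kin_fields)) {
      p[[kin_fields[j]]] <- p[[kin_fields[j]]] * mult$kin[i, j]
    }
    ## a kinetic draw may not invert the rise/decay ordering at the default
    ## CVs; guard against pathological user-set CVs anyway
    if (p$tau_ca_rise >= p$tau_ca_decay) {
      p$tau_ca_rise <- 0.95 * p$tau_ca_decay
    }
    p$muscle_id <- sprintf("%s_%02d", p$group_label, i)
    validate_muscle_params(p)
  })
}
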