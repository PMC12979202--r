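# Cohort with a planted HPV effect on the LSIL-cell burden: every slide NILM,
# HPV split 50/50 and always observed, LSIL counts NB(mu = 2, size = 0.8) on
# HPV- slides and NB(mu = 20, size = 0.8) on HPV+ slides (10x mean). CMD
# noise is tight (concentration 64) so gated counts equal true counts.
planted_cfg <- function(n_slides, seed) {
  dx <- bethesda_categories()
  sim_config(
    n_slides = n_slides, centres = "C", seed = seed,
    diagnosis_mixture = c(1, 0, 0, 0, 0, 0),
    hpv_model = list(p_positive = setNames(rep(0.5, 6), dx), p_missing = 0),
    cellularity = list(meanlog = log(400), sdlog = 0.3),
    abnormal_burden = list(
      lsil_mu = setNames(c(2, 0, 0, 0, 0, 0), dx),
      hsil_mu = setNames(rep(0, 6), dx),
      adeno_mu = setNames(rep(0, 6), dx),
      size = 0.8, hpv_multiplier = 10
    ),
    cmd_noise = list(true = c(16, 2), off = c(0.5, 10),
                     confusion = list(pairs = list(), prob = 0,
                                      shape = c(2.5, 4.5)),
                     concentration = 64)
  )
}

# exact delta / AUC of the planted comparison by numerical integration of the
# two negative-binomial pmfs
planted_oracle <- function(mu_neg = 2, mu_pos = 20, size = 0.8) {
  upper <- qnbinom(1 - 1e-13, size = size, mu = mu_pos) + 10
  supp <- 0:upper
  bf_planted_stats(dnbinom(supp, size = size, mu = mu_pos),
                   dnbinom(supp, size = size, mu = mu_neg))
}

# cohort whose diagnostic groups genuinely overlap in lesion burden, so
# endpoint AUCs sit well below 1 and bootstrap intervals have width
overlap_cfg <- function(n_slides, seed) {
  dx <- bethesda_categories()
  sim_config(
    n_slides = n_slides, centres = "C", seed = seed,
    cellularity = list(meanlog = log(250), sdlog = 0.4),
    abnormal_burden = list(
      lsil_mu = setNames(c(2, 4, 12, 8, 8, 8), dx),
      hsil_mu = setNames(c(0.8, 1.5, 3, 8, 15, 20), dx),
      adeno_mu = setNames(rep(0.1, 6), dx),
      size = 0.6, hpv_multiplier = 2
    )
  )
}
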