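#' Default synthetic study: four groups with planted neurodynamic effects
#'
#' Builds the [effect_spec()] of the package's reference synthetic study: a
#' four-group cohort (typically developing controls `TD`, `ASD`, `ADHD`,
#' and the comorbid `ASD_ADHD`) of seven-network subjects whose global
#' dynamics, local timescales and symptom scores carry known planted
#' effects, sized like a single-site pediatric rsfMRI study (30 subjects
#' per group, 175 timepoints at TR = 2 s).
#'
#' All groups share one base energy landscape (a fixed seven-node Ising
#' model with six local minima, two of them — states A and B — clearly
#' deepest), scaled in depth per group: deeper for `ASD`, shallower for
#' `ADHD` and `ASD_ADHD`. On top of the landscape, groups differ in
#' dynamical speed (Metropolis steps per recorded timepoint): the
#' `ADHD`-like groups evolve faster, which simultaneously shortens every
#' node's intrinsic neural timescale and raises the per-timepoint frequency
#' of completed indirect transitions — the mechanistic chain
#' (unstable local activity -> frequent indirect transitions) that the
#' mediation stage is meant to recover. Subject-level log-normal jitter on
#' speed and depth provides the within-group variability that symptom
#' correlations and mediation run on.
#'
#' Symptom scores are planted linearly on each subject's realized indirect
#' transition frequencies: autistic socio-communicational severity
#' (`adir_social`, ASD groups) decreases with `freq_ACDB`; hyperactivity
#' (`cprs_hyper`, ADHD and TD) increases with `freq_ACDEFB`; restricted and
#' repetitive behaviour (`adir_rrb`, comorbid group; lower = more cognitively
#' unstable) decreases with `freq_ACFB`. Slopes and noise levels are chosen
#' so that within-group correlations fall in the 0.4-0.7 band typical of
#' symptom-dynamics associations.
#'
#' @param seed master seed of the generated cohort.
#' @param n_subjects_per_group subjects per group.
#' @param n_timepoints timepoints per subject.
#' @return an [effect_spec()].
#' @export
default_study_spec <- function(seed = 1L, n_subjects_per_group = 30,
                               n_timepoints = 175) {
  base <- base_study_model()
  models <- list(
    TD = base,
    ASD = scale_model(base, 1.3),
    ADHD = scale_model(base, 0.7),
    ASD_ADHD = scale_model(base, 0.85)
  )
  effect_spec(
    models,
    n_subjects_per_group = n_subjects_per_group,
    n_timepoints = n_timepoints,
    snr = 8,
    steps_per_tr = c(TD = 2, ASD = 2, ADHD = 6, ASD_ADHD = 4),
    speed_jitter_sd = 0.5,
    temperature_jitter_sd = 0.15,
    symptom_slopes = list(
      adir_social = list(feature = "freq_ACDB", slope = -250, noise_sd = 3.5,
                         intercept = 26, groups = c("ASD", "ASD_ADHD")),
      cprs_hyper = list(feature = "freq_ACDEFB", slope = 900, noise_sd = 10,
                        intercept = 45, groups = c("ADHD", "TD")),
      adir_rrb = list(feature = "freq_ACFB", slope = -250, noise_sd = 1.5,
                      intercept = 7, groups = "ASD_ADHD")
    ),
    tr_seconds = 2,
    seed = seed
  )
}

#' @rdname default_study_spec
#' @details `base_study_model()` returns the shared base landscape: a
#'   seven-node pairwise model with uniform(-0.3, 0.3) fields and couplings
#'   (fixed internal seed), selected so that the landscape has exactly six
#'   local minima, no saddle-ambiguous patterns, negligible probability mass
#'   on the two uniform patterns (which per-timepoint-mean binarization
#'   cannot represent), and nonzero traffic along all three canonical
#'   indirect-transition templates. Nodes carry the names of the seven
#'   canonical resting-state networks.
#' @export
base_study_model <- function() {
  m <- make_ising_model(7, field_scale = 0.3, coupling_scale = 0.6,
                        seed = 135, label = "base study landscape")
  m$node_names <- c("VIS", "SMN", "DAN", "VAN", "LIM", "FPCN", "DMN")
  m
}

#' @rdname default_study_spec
#' @details `default_study_config()` returns the matching pipeline
#'   configuration: TD as reference group, and one mediation analysis on the
#'   combined ADHD + TD sample testing whether the dorsal-attention-node
#'   intrinsic timescale (`int_DAN`) drives hyperactivity through the
#'   `A-[C/D-E/F]-B` transition frequency. The mediation pools the
#'   case-control pair so that the group-driven variation in local
#'   timescale contributes to the x -> m path, as in case-control mediation
#'   designs.
#' @param n_boot bootstrap replicates for the mediation stage.
#' @export
default_study_config <- function(seed = 1L, n_boot = 5000) {
  study_config(
    seed = seed,
    n_boot = n_boot,
    reference_group = "TD",
    reference_model = base_study_model(),
    tr_seconds = 2,
    mediations = list(
      list(group = c("ADHD", "TD"), x = "int_DAN", m = "freq_ACDEFB",
           y = "cprs_hyper")
    )
  )
}
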