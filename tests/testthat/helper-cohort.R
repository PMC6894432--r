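# Shared synthetic cohorts and pipeline runs, cached so that several
# test files can reuse the same simulated data without regenerating it.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cohort_cache))
    assign(key, expr, envir = .cohort_cache)
  get(key, envir = .cohort_cache)
}

default_cohort <- function(seed) {
  cached(paste0("cohort", seed),
         generate_cohort(cohort_config(seed = seed)))
}

default_run <- function(seed) {
  cached(paste0("run", seed), {
    out <- file.path(tempdir(), paste0("csrun", seed))
    run_pipeline(default_run_config(seed = seed, outdir = out))
  })
}

# Map each detected module to the planted module it overlaps most.
match_detected_module <- function(assignment, truth, planted_module) {
  planted <- truth$modules$gene_id[truth$modules$module == planted_module]
  mods <- setdiff(unique(assignment), "unassigned")
  if (!length(mods)) return(NA_character_)
  ov <- vapply(mods, function(mm)
    sum(names(assignment)[assignment == mm] %in% planted), 0L)
  mods[which.max(ov)]
}

truth_label_vector <- function(assignment, truth) {
  lab <- stats::setNames(rep("none", length(assignment)), names(assignment))
  lab[truth$modules$gene_id] <- truth$modules$module
  lab
}

# A deliberately small toy cohort for fast structural tests.
toy_cohort <- function(seed = 99) {
  cached(paste0("toy", seed),
         generate_cohort(cohort_config(
           seed = seed, n_pairs = 12, n_mrna = 120, n_lncrna = 80,
           n_mirna = 40, n_modules = 2, module_size = 15,
           n_triplets = 6, n_candidate_lnc = 2, triplets_per_candidate = 2,
           n_triplet_mirnas = 6, n_risk_lnc = 1,
           frac_de = 0.15, targets_per_mirna = 8)))
}
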