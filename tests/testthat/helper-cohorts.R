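# Shared small-cohort builders for the test suite.

small_sig_frame <- function(n_pos = 3, n_neg = 3, size = 20, gamma = 0.5) {
  data.frame(
    name = c(sprintf("POSSIG%d", seq_len(n_pos)),
             sprintf("NEGSIG%d", seq_len(n_neg))),
    size = size,
    sign = c(rep(1, n_pos), rep(-1, n_neg)),
    gamma = gamma)
}

quick_cohort <- function(seed = 1, n = 120, module = 20, rho = 0.5,
                         background = 100, signatures = NULL, ...) {
  simulate_cohort(simulation_config(
    n_samples = n, n_background_genes = background, anchors = "JAG1",
    module_size = module, target_rho = rho, signatures = signatures,
    seed = seed, ...))
}

# Signature gene sets only (drop the planted anchor-module sets).
signature_sets <- function(cohort) {
  keep <- !grepl("-module$", names(cohort$true_signatures))
  gene_set_collection(unclass(cohort$true_signatures)[keep])
}
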