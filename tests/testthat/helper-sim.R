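# Small shared simulations, built once per test run.
local_sim_cache <- new.env(parent = emptyenv())

small_sim <- function(key = "default", ...) {
  if (!exists(key, envir = local_sim_cache)) {
    assign(key, simulate_two_pop(sim_config(...)), envir = local_sim_cache)
  }
  get(key, envir = local_sim_cache)
}

# one 400-kb contig, 20 + 20 diploids, one sweep, one causal SNP
small_sweep_sim <- function() {
  small_sim("sweep", seed = 101, n_contigs = 1, contig_length_bp = 4e5,
            sweep_intervals = data.frame(contig = "ctg01",
                                         start = 200001L, end = 240000L),
            n_genes = 10)
}

# neutral small genome
small_neutral_sim <- function() {
  small_sim("neutral", seed = 202, n_contigs = 2, contig_length_bp = 4e5,
            sweeps_per_contig = 0, n_causal_phenotype_snps = 0,
            n_genes = 10)
}
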