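# full simulated screen: reference -> library -> selection -> error-free
# junction reads -> tag trim -> mapping -> indices -> candidate table.
# Returns the candidate table plus the planted gene id.
run_simulated_screen <- function(seed, n_genes = 50, n_mutants = 1e4,
                                 base_rate = 0.01, effect = 20,
                                 planted_gene_index = 25,
                                 tag = "TAAGAGACAG") {
  r <- generate_reference(n_genes, seed = seed)
  ann <- r$annotation
  planted <- ann$gene_id[planted_gene_index]
  effects <- if (effect == 1) numeric(0) else setNames(effect, planted)
  lib <- simulate_insertion_library(r$assembly, n_mutants, seed = seed + 500L)
  out <- apply_conjugation_selection(lib, selection_model(base_rate, effects),
                                     ann, seed = seed + 1000L)
  rin <- synthesize_reads(lib, r$assembly, tag = tag, read_length = 50,
                          error_rate = 0, depth_per_mutant = 10,
                          seed = seed + 1500L)
  rout <- synthesize_reads(out, r$assembly, tag = tag, read_length = 50,
                           error_rate = 0, depth_per_mutant = 10,
                           seed = seed + 2000L)
  sc <- run_screen(rin, rout, r$assembly, ann, tag = tag)
  list(candidates = sc$candidates, planted = planted)
}
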