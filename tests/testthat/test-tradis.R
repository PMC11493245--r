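test_that("tag matching keeps reads within the mismatch budget and trims", {
  rs <- read_set(c("r1", "r2", "r3"),
                 c("ACGTAAAAAA",   # exact tag
                   "ACGAAAAAAA",   # 1 mismatch in tag
                   "TTTTAAAAAA"),  # 3 mismatches
                 rep("IIIIIIIIII", 3), tag = "ACGT")
  t0 <- match_and_trim_tag(rs, "ACGT", max_mismatches = 0)
  expect_equal(t0$seq, "AAAAAA")
  expect_equal(attr(t0, "kept"), 1)
  expect_equal(attr(t0, "discarded"), 2)

  # boundary: max_mismatches + 1 mismatches is discarded, exactly max kept
  t1 <- match_and_trim_tag(rs, "ACGT", max_mismatches = 1)
  expect_equal(attr(t1, "kept"), 2)
  t2 <- match_and_trim_tag(rs, "ACGT", max_mismatches = 2)
  expect_equal(attr(t2, "kept"), 2)

  expect_error(match_and_trim_tag(rs, strrep("A", 20)), "longer")

  # round trip with the simulator: error-free reads are 100% retained
  r <- generate_reference(5, seed = 3)
  lib <- simulate_insertion_library(r$assembly, 500, seed = 4)
  reads <- synthesize_reads(lib, r$assembly, tag = "TAAGAGACAG",
                            read_length = 50, error_rate = 0,
                            depth_per_mutant = 2, seed = 5)
  tt <- match_and_trim_tag(reads, "TAAGAGACAG", 0)
  expect_equal(attr(tt, "discarded"), 0)
  expect_equal(length(tt), length(reads))
})

test_that("junction mapping follows the strand/coordinate convention", {
  set.seed(31)
  refstr <- random_dna(2000)
  ref <- tiny_ref(c(chr = refstr), circular = FALSE)

  # read whose post-tag 25-mer occurs once forward at offset 1000
  fwd_read <- substr(refstr, 1001, 1040)
  rev_window <- substr(refstr, 1476, 1500)   # 0-based 1475..1499
  rev_read <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rev_window)))
  rs <- read_set(c("f", "r"), c(fwd_read, paste0(rev_read, "AAAAACCCCCGGGGG")),
                 c(strrep("I", 40), strrep("I", 40)), tag = "")
  sites <- map_insertions(rs, ref, seed_length = 25, label = "input")
  expect_equal(nrow(sites), 2)
  expect_true(any(sites$position == 1000 & sites$strand == "+"))
  # '-' junction is the window's right edge (0-based 1499)
  expect_true(any(sites$position == 1499 & sites$strand == "-"))

  # ambiguous seed (two loci) is discarded and counted
  dup <- paste0(strrep("A", 30), substr(refstr, 1, 40))
  ref2 <- tiny_ref(c(chr = paste0(dup, dup)), circular = FALSE)
  rs2 <- read_set("a", substr(dup, 31, 70), strrep("I", 40), tag = "")
  s2 <- map_insertions(rs2, ref2, seed_length = 25)
  expect_equal(nrow(s2), 0)
  expect_equal(attr(s2, "ambiguous"), 1)

  # unmatched seed is discarded and counted
  rs3 <- read_set("u", strrep("T", 40), strrep("I", 40), tag = "")
  s3 <- map_insertions(rs3, ref, seed_length = 25)
  expect_equal(attr(s3, "unmapped"), 1)

  expect_error(map_insertions(rs, tiny_ref(character(0)), 25), "empty")
})

test_that("error-free reads recover the insertion site set exactly", {
  r <- generate_reference(10, seed = 13)
  lib <- simulate_insertion_library(r$assembly, 2000, seed = 14)
  reads <- synthesize_reads(lib, r$assembly, tag = "TAAGAGACAG",
                            read_length = 50, error_rate = 0,
                            depth_per_mutant = 3, seed = 15)
  trimmed <- match_and_trim_tag(reads, "TAAGAGACAG", 0)
  sites <- map_insertions(trimmed, r$assembly, seed_length = 25)
  expect_equal(attr(sites, "ambiguous"), 0)
  expect_equal(attr(sites, "unmapped"), 0)
  keys_lib <- sort(paste(lib$replicon, lib$position, lib$strand))
  keys_map <- sort(paste(sites$replicon, sites$position, sites$strand))
  expect_identical(keys_map, keys_lib)
  # read counts are depth * abundance at every site
  m <- match(paste(sites$replicon, sites$position, sites$strand),
             paste(lib$replicon, lib$position, lib$strand))
  expect_equal(sites$read_count, as.integer(lib$abundance[m] * 3))
})

test_that("insertion indices follow the per-bp, library-normalized definition", {
  # constructed case: gene of 600 bp with 12 unique sites, library total 1200
  ann <- data.frame(gene_id = "g1", replicon = "chr", start = 100L,
                    end = 700L, strand = "+")
  pos <- c(seq(110, 650, length.out = 12),            # 12 inside the gene
           seq(1000, 2187, length.out = 1188))        # 1188 outside
  sites <- structure(
    data.frame(replicon = "chr", position = as.integer(round(pos)),
               strand = "+", read_count = 1L),
    label = "input", class = c("insertion_sites", "data.frame"))
  idx <- compute_insertion_index(sites, ann)
  expect_equal(idx$unique_sites, 12L)
  expect_equal(idx$raw_density, 12 / 600)
  expect_equal(idx$insertion_index, (12 / 600) / 1200)

  # empty site set -> all indices zero
  empty <- structure(
    data.frame(replicon = character(0), position = integer(0),
               strand = character(0), read_count = integer(0)),
    label = "input", class = c("insertion_sites", "data.frame"))
  expect_true(all(compute_insertion_index(empty, ann)$insertion_index == 0))

  # genic unique sites never exceed the library total
  r <- generate_reference(10, seed = 23)
  lib <- simulate_insertion_library(r$assembly, 5000, seed = 24)
  s <- sites_from_library(lib)
  ix <- compute_insertion_index(s, r$annotation)
  expect_lte(sum(ix$unique_sites), nrow(s))

  # uniform library: per-gene indices agree within binomial sampling error
  p_gene <- (ix$end - ix$start) / sum(replicon_lengths(r$assembly))
  sd_sites <- sqrt(nrow(s) * p_gene * (1 - p_gene))
  expect_true(all(abs(ix$unique_sites - nrow(s) * p_gene) < 5 * sd_sites))
})

test_that("candidate calling reproduces the printed fold-change arithmetic", {
  mk_idx <- function(gene, index, label) {
    structure(data.frame(gene_id = gene, replicon = "plasmid",
                         start = seq_along(gene) * 1000L,
                         end = seq_along(gene) * 1000L + 600L,
                         length = 600L, unique_sites = NA_integer_,
                         raw_density = NA_real_, insertion_index = index),
              label = label,
              class = c("insertion_index_table", "data.frame"))
  }
  # the fold change printed for the surface-exclusion gene: 0.0622/0.0100
  inp <- mk_idx(c("vcrx085", "vcrx001"), c(0.0100, 0.0300), "input")
  out <- mk_idx(c("vcrx085", "vcrx001"), c(0.0622, 0.0300), "output")
  cand <- call_candidates(inp, out, threshold = 5, pseudocount = 0)
  expect_equal(cand$ratio[cand$gene_id == "vcrx085"], 6.22)
  expect_true(cand$candidate[cand$gene_id == "vcrx085"])
  # equal indices give ratio 1, not a candidate
  expect_equal(cand$ratio[cand$gene_id == "vcrx001"], 1)
  expect_false(cand$candidate[cand$gene_id == "vcrx001"])

  # a gene absent from one table is scored as zero and flagged
  out2 <- mk_idx("vcrx085", 0.0622, "output")
  cand2 <- call_candidates(inp, out2, threshold = 5)
  expect_true(cand2$missing[cand2$gene_id == "vcrx001"])
  expect_equal(cand2$output_index[cand2$gene_id == "vcrx001"], 0)
  # default pseudocount: half the smallest nonzero index
  expect_equal(attr(cand2, "pseudocount"), 0.0100 / 2)
  # output sorted by coordinate
  expect_equal(cand$gene_id, c("vcrx085", "vcrx001"))
})

test_that("index ratios are stable under uniform down-sampling", {
  r <- generate_reference(20, seed = 33)
  ann <- r$annotation
  planted <- ann$gene_id[5]
  lib <- simulate_insertion_library(r$assembly, 5e4, seed = 34)
  out <- apply_conjugation_selection(
    lib, selection_model(0.05, setNames(10, planted)), ann, seed = 35)
  ratio_of <- function(lib_in, lib_out) {
    cand <- call_candidates(
      compute_insertion_index(sites_from_library(lib_in), ann),
      compute_insertion_index(sites_from_library(lib_out), ann))
    cand$ratio[cand$gene_id == planted]
  }
  full <- ratio_of(lib, out)
  thin <- function(l, frac, seed) {
    set.seed(seed)
    kept <- rbinom(nrow(l), as.integer(l$abundance), frac)
    insertion_library(l$replicon[kept > 0], l$position[kept > 0],
                      l$strand[kept > 0], kept[kept > 0],
                      label = library_label(l))
  }
  sub <- replicate(6, ratio_of(thin(lib, 0.5, sample.int(1e6, 1)),
                               thin(out, 0.5, sample.int(1e6, 1))))
  expect_lt(abs(mean(sub) - full) / full, 0.2)
})

test_that("neutral selection rarely crosses the candidate threshold", {
  # false-positive control at the library level: all effects 1, >= 20 seeds
  r <- generate_reference(50, seed = 2)
  ann <- r$annotation
  fp <- 0; n_genes <- 0
  for (s in 1:20) {
    lib <- simulate_insertion_library(r$assembly, 1e4, seed = 200 + s)
    out <- apply_conjugation_selection(lib, selection_model(0.01), ann,
                                       seed = 300 + s)
    cand <- call_candidates(
      compute_insertion_index(sites_from_library(lib), ann),
      compute_insertion_index(sites_from_library(out), ann))
    fp <- fp + sum(cand$candidate)
    n_genes <- n_genes + nrow(cand)
  }
  expect_lt(fp / n_genes, 0.01)
})

test_that("screen tables round-trip through their TSV writers", {
  r <- generate_reference(5, seed = 51)
  lib <- simulate_insertion_library(r$assembly, 300, seed = 52)
  s <- sites_from_library(lib)
  f1 <- tempfile(fileext = ".tsv")
  write_sites_tsv(s, f1)
  back <- read.delim(f1)
  expect_equal(back$position, s$position)
  expect_equal(back$read_count, s$read_count)

  lt <- tempfile(fileext = ".tsv")
  write_library_tsv(lib, lt)
  lib2 <- read_library_tsv(lt)
  expect_identical(as.data.frame(lib2), as.data.frame(lib))
  expect_identical(library_label(lib2), "input")
})
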