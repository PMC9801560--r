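test_that("FASTA round trip preserves records, order, and case-normalizes", {
  set.seed(51)
  recs <- c(one = random_seq(40), two = tolower(random_seq(25)), three = random_seq(40))
  path <- tempfile(fileext = ".fa")
  write_fasta(recs, path)
  back <- read_fasta(path)
  expect_identical(names(back), c("one", "two", "three"))
  expect_identical(unname(back), unname(toupper(recs)))
  unlink(path)
})

test_that("records with ambiguity codes are rejected by id", {
  path <- tempfile(fileext = ".fa")
  writeLines(c(">ok", "ACGT", ">badrec", "ACNNT"), path)
  expect_error(read_fasta(path), "badrec")
  unlink(path)
})

test_that("window extraction yields one positive and n negatives per gene", {
  set.seed(52)
  genome <- random_seq(5000)
  ds <- extract_windows(genome, tss_positions = c(400, 2000),
                        gene_ends = c(1800, 4500), n_neg_per_gene = 10,
                        seed = 7)
  expect_equal(sum(ds$windows$label == 1), 2)
  expect_equal(sum(ds$windows$label == -1), 20)
  expect_equal(ds$ir, 10)
  expect_true(all(nchar(ds$windows$seq201) == 201))
  expect_true(all(nchar(ds$windows$seq300) == 300))
  # positive windows are centred on the TSS (site at 0-based index 100/150)
  expect_equal(substr(ds$windows$seq300[1], 151, 151), substr(genome, 400, 400))
  expect_equal(substr(ds$windows$seq201[1], 101, 101), substr(genome, 400, 400))
  # negatives drawn from 100 bp downstream of the TSS up to the gene end
  neg_pos <- ds$windows$source_position[ds$windows$label == -1][1:10]
  expect_true(all(neg_pos >= 500 & neg_pos <= 1800))
  # same seed, same dataset
  ds2 <- extract_windows(genome, c(400, 2000), c(1800, 4500), 10, seed = 7)
  expect_identical(ds$windows, ds2$windows)
  expect_error(extract_windows(genome, 100, 1500), "full 201")
  # an infeasible gene is skipped with a warning; usable genes still emit
  expect_warning(ds3 <- extract_windows(genome, c(400, 2000), c(450, 4500),
                                        10, seed = 1),
                 "skipped")
  expect_equal(nrow(ds3$windows), 11)
})

test_that("undersampling keeps the minority class and hits the target ratio", {
  set.seed(53)
  ds <- make_synthetic(n_pos = 10, n_neg = 100, seed = 1)
  u1 <- undersample(ds, target_ir = 1, seed = 2)
  expect_equal(sum(u1$windows$label == 1), 10)
  expect_equal(sum(u1$windows$label == -1), 10)
  u2 <- undersample(ds, target_ir = 2, seed = 2)
  expect_equal(sum(u2$windows$label == -1), 20)
  expect_identical(undersample(ds, 1, seed = 9)$windows,
                   undersample(ds, 1, seed = 9)$windows)
  expect_true(all(ds$windows$id[ds$windows$label == 1] %in% u1$windows$id))
  expect_error(undersample(ds, target_ir = 20, seed = 1), "exceeds")
})

test_that("synthetic positives carry the requested AT enrichment", {
  ds <- make_synthetic(n_pos = 250, n_neg = 250, at_bias = 0.15, seed = 4)
  # measure outside the planted (jittered) motif, whose own AT content
  # would otherwise confound the bias estimate
  core_at <- function(s) {
    core <- strsplit(substr(s, 130, 181), "")[[1]]
    mean(core %in% c("A", "T"))
  }
  at_pos <- vapply(ds$windows$seq300[ds$windows$label == 1], core_at, numeric(1))
  at_neg <- vapply(ds$windows$seq300[ds$windows$label == -1], core_at, numeric(1))
  expect_lt(abs(mean(at_pos) - mean(at_neg) - 0.15), 0.035)
})

test_that("null construction is seeded, reproducible, and signal-free", {
  null1 <- make_synthetic(n_pos = 30, n_neg = 60, at_bias = 0,
                          motif_spec = list(consensus = "TATAAA", offset = -30,
                                            mutation_rate = 1),
                          seed = 6)
  null2 <- make_synthetic(n_pos = 30, n_neg = 60, at_bias = 0,
                          motif_spec = list(consensus = "TATAAA", offset = -30,
                                            mutation_rate = 1),
                          seed = 6)
  expect_identical(null1$windows, null2$windows)
  # base composition indistinguishable between classes in the null
  at_frac <- function(s) mean(strsplit(s, "")[[1]] %in% c("A", "T"))
  ap <- vapply(null1$windows$seq300[null1$windows$label == 1], at_frac, numeric(1))
  an <- vapply(null1$windows$seq300[null1$windows$label == -1], at_frac, numeric(1))
  expect_gt(t.test(ap, an)$p.value, 0.01)
  expect_error(make_synthetic(10, 10, at_bias = 0.9), "at_bias")
})

test_that("dataset FASTA + labels round trip", {
  ds <- make_synthetic(n_pos = 5, n_neg = 15, seed = 8)
  fa <- tempfile(fileext = ".fa"); lb <- tempfile(fileext = ".tsv")
  write_dataset(ds, fa, lb)
  back <- read_dataset(fa, lb)
  expect_identical(back$windows$seq300, ds$windows$seq300)
  expect_identical(back$windows$label, ds$windows$label)
  expect_identical(back$windows$seq201, ds$windows$seq201)
  unlink(c(fa, lb))
})

test_that("profile tables are written in long tab-separated form", {
  p <- pbdtss:::new_opening_profile(c(0.1, 0.2), "w1", 345, 8, "participation", TRUE)
  path <- tempfile(fileext = ".tsv")
  write_profiles(p, path)
  tab <- read.delim(path)
  expect_identical(names(tab),
                   c("sequence_id", "position_index", "temperature_K", "m",
                     "probability"))
  expect_equal(tab$position_index, c(0, 1))
  expect_equal(tab$probability, c(0.1, 0.2))
  unlink(path)
})
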