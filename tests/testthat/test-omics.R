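toy_profile <- function() {
  mutation_profile(tibble::tibble(
    sample_id = c(rep("P1", 8), rep("P2", 3), rep("P3", 2)),
    gene = c("TP53", "KRAS", "APC", "MSH2", "BRAF", "TTN", "EGFR", "PIK3CA",
             "MSH2", "MSH2", "TP53",
             "KRAS", "KRAS"),
    variant_class = c("missense", "missense", "nonsense", "missense", "INS",
                      "DEL", "synonymous", "synonymous",
                      "synonymous", "synonymous", "missense",
                      "DEL", "DEL")))
}

test_that("TMB counts nonsynonymous rows over the exome size", {
  prof <- toy_profile()
  expect_equal(tmb(prof, "P1"), 6 / 38)  # 5 point + 1 INS/DEL... see below
  # explicit arithmetic cases
  big <- mutation_profile(tibble::tibble(
    sample_id = "S", gene = sprintf("G%d", 1:380),
    variant_class = "missense"))
  expect_equal(tmb(big, "S"), 10)
  syn_only <- mutation_profile(tibble::tibble(
    sample_id = "S", gene = c("A", "B"), variant_class = "synonymous"))
  expect_equal(tmb(syn_only, "S"), 0)
  expect_error(tmb(prof, "nope"), "unknown sample")
})

test_that("mixed toy profile counts INS as nonsynonymous", {
  prof <- mutation_profile(tibble::tibble(
    sample_id = "M",
    gene = sprintf("G%d", 1:8),
    variant_class = c(rep("missense", 5), "synonymous", "synonymous", "INS")))
  expect_equal(tmb(prof, "M"), 6 / 38)
})

test_that("INDEL load counts INS and DEL rows, duplicates separately", {
  prof <- mutation_profile(tibble::tibble(
    sample_id = "S",
    gene = sprintf("G%d", 1:9),
    variant_class = c("INS", "INS", "INS", "DEL", "DEL",
                      "missense", "missense", "missense", "missense")))
  expect_equal(indel_load(prof, "S"), 5)
  none <- mutation_profile(tibble::tibble(sample_id = "S", gene = "A",
                                          variant_class = "missense"))
  expect_equal(indel_load(none, "S"), 0)
  dup <- mutation_profile(tibble::tibble(sample_id = c("S", "S"),
                                         gene = c("A", "A"),
                                         variant_class = c("DEL", "DEL")))
  expect_equal(indel_load(dup, "S"), 2)
})

test_that("pathway deficiency requires a nonsynonymous hit in the set", {
  prof <- toy_profile()
  expect_equal(pathway_deficiency(prof, "P1", mmr_genes), "deficient")
  expect_equal(pathway_deficiency(prof, "P2", mmr_genes), "proficient")
  expect_equal(pathway_deficiency(prof, "absent", mmr_genes), "proficient")
  expect_error(pathway_deficiency(prof, "P1", character(0)), "empty gene set")
})

test_that("omics scalars are invariant to row order", {
  prof <- toy_profile()
  shuffled <- mutation_profile(prof[sample(nrow(prof)), ])
  attr(shuffled, "exome_size_mb") <- attr(prof, "exome_size_mb")
  for (s in c("P1", "P2", "P3")) {
    expect_equal(tmb(shuffled, s), tmb(prof, s))
    expect_equal(indel_load(shuffled, s), indel_load(prof, s))
    expect_equal(pathway_deficiency(shuffled, s), pathway_deficiency(prof, s))
  }
})

test_that("MAF column names and classes map through the synonym table", {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(
    Tumor_Sample_Barcode = c("T1", "T1", "T1"),
    Hugo_Symbol = c("MLH1", "TP53", "BRAF"),
    Variant_Classification = c("Frame_Shift_Ins", "Silent", "Missense_Mutation")),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  prof <- read_mutation_profile(path)
  expect_equal(sort(prof$variant_class), c("INS", "missense", "synonymous"))
  expect_equal(indel_load(prof, "T1"), 1)
  expect_equal(pathway_deficiency(prof, "T1"), "deficient")

  expect_error(mutation_profile(data.frame(
    sample_id = "x", gene = "Y", Variant_Classification = "Weird_Class")),
    "unknown Variant_Classification")
})

test_that("min-max normalisation handles its degenerate case", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_warning(flat <- minmax_normalize(c(5, 5)), "constant")
  expect_equal(flat, c(0.5, 0.5))
  v <- minmax_normalize(c(1, 3, 9))
  expect_equal(minmax_normalize(v), v)  # idempotent when non-degenerate
})

test_that("CYT score is the pseudocounted geometric mean of GZMA and PRF1", {
  expr <- rbind(GZMA = c(A = 3, B = 7, C = 0), PRF1 = c(A = 8, B = 7, C = 0))
  expect_equal(cyt_score(expr, "A"), 5)            # sqrt(4 * 9) - 1
  expect_equal(cyt_score(expr, "B"), 7)            # equal inputs pass through
  expect_equal(cyt_score(expr, "C"), 0)
  expect_error(cyt_score(rbind(GZMA = c(A = 1)), "A"), "PRF1")
})

test_that("gene-set score averages log2 over present members with a warning", {
  full <- matrix(1, nrow = 8, ncol = 1,
                 dimnames = list(cd8_t_effector_genes, "S"))
  expect_equal(gene_set_score(full, "S"), 1)
  zero <- matrix(0, nrow = 8, ncol = 1,
                 dimnames = list(cd8_t_effector_genes, "S"))
  expect_equal(gene_set_score(zero, "S"), 0)
  part <- matrix(3, nrow = 4, ncol = 1,
                 dimnames = list(cd8_t_effector_genes[1:4], "S"))
  expect_warning(v <- gene_set_score(part, "S"), "4 missing")
  expect_equal(v, 2)
  other <- matrix(1, nrow = 1, ncol = 1, dimnames = list("ACTB", "S"))
  expect_error(gene_set_score(other, "S"), "none of the gene-set members")
})

test_that("Spearman correlation matches the rank-then-Pearson oracle", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearman_corr(x, x)$rho, 1)
  expect_equal(spearman_corr(x, -x)$rho, -1)
  set.seed(61)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    a <- rnorm(n); b <- 0.5 * a + rnorm(n)
    got <- spearman_corr(a, b)
    expect_equal(got$rho, cor(rank(a), rank(b)), tolerance = 1e-12)
    ref <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  }
  expect_error(spearman_corr(1:4, 1:5), "equal length")
  expect_warning(const <- spearman_corr(rep(1, 5), 1:5), "constant")
  expect_true(is.na(const$rho))
})
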