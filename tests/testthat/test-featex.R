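test_that("pseudo-AA composition is a probability vector matching the brute-force oracle", {
  sc <- aa_property_scales()
  # standardization invariant of the bundled scales
  expect_equal(unname(colMeans(sc)), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(apply(sc, 2, sd)), rep(1, 3), tolerance = 1e-9)

  # homopolymer forces all sequence-order factors to zero
  v <- pseudo_aa("AAAAAAAA", lambda = 4)
  expect_equal(v[["pseAA_A"]], 1)
  expect_equal(unname(v[paste0("pseAA_theta", 1:4)]), rep(0, 4))

  # exact agreement with the independent double-loop oracle
  v2 <- pseudo_aa("ARNDARND", lambda = 2, w = 0.05,
                  scales = sc[, 1, drop = FALSE])
  expect_equal(unname(v2),
               oracle_pseudo_aa("ARNDARND", 2, 0.05, sc[, 1, drop = FALSE]),
               tolerance = 1e-12)

  # probability-vector property over random proteins, all three scales
  set.seed(401)
  aas <- rownames(sc)
  for (i in 1:100) {
    s <- paste(sample(aas, sample(20:80, 1), replace = TRUE), collapse = "")
    lam <- sample(1:10, 1)
    v <- pseudo_aa(s, lambda = lam, w = 0.05)
    expect_equal(sum(v), 1, tolerance = 1e-9)
    expect_true(all(v >= 0))
    expect_equal(unname(v), oracle_pseudo_aa(s, lam, 0.05, sc),
                 tolerance = 1e-12)
  }

  expect_error(pseudo_aa("MKV", lambda = 4), "must exceed lambda")
  expect_warning(pseudo_aa("MKVXXLANDER", lambda = 2), "stripped")
})

test_that("dinucleotide property averages match the naive window loop and ignore U/T case", {
  tab <- read_dinuc_table()
  expect_equal(dim(tab), c(12L, 16L))
  p <- rownames(tab)[1]
  expect_equal(unname(dinuc_features("AAAA", tab, p)), tab[p, "AA"])
  expect_equal(unname(dinuc_features("ACAC", tab, "twist")),
               (2 * tab["twist", "AC"] + tab["twist", "CA"]) / 3)
  # U <-> T substitution invariance
  expect_equal(dinuc_features("ACGU", tab), dinuc_features("ACGT", tab))
  # windows containing N are skipped
  expect_equal(unname(dinuc_features("AANAA", tab, p)), tab[p, "AA"])
  # brute-force oracle on random sequences
  set.seed(402)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    for (pr in sample(rownames(tab), 3)) {
      expect_equal(unname(dinuc_features(s, tab, pr)),
                   oracle_dinuc(s, tab, pr), tolerance = 1e-12)
    }
  }
  expect_error(dinuc_features("A", tab), "length >= 2")
  expect_error(dinuc_features("ACGT", tab, "no_such_property"), "unknown")
})

test_that("user property tables load from the documented TSV dialect", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  dn <- c("AA", "AC", "AG", "AT", "CA", "CC", "CG", "CT",
          "GA", "GC", "GG", "GT", "TA", "TC", "TG", "TT")
  writeLines(c(paste(c("property", dn), collapse = "\t"),
               paste(c("custom", 1:16), collapse = "\t")), tf)
  tab <- read_dinuc_table(tf)
  expect_equal(rownames(tab), "custom")
  expect_equal(unname(dinuc_features("AAAT", tab, "custom")),
               (1 + 1 + 4) / 3)
  writeLines(c("property\tAA", "x\t1"), tf)
  expect_error(read_dinuc_table(tf), "columns")
})

test_that("gc_content handles strands, RNA and ambiguity codes", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ACGTN"), 0.5)
  expect_equal(gc_content("ACGU"), 0.5)
  expect_error(gc_content("NNN"), "no unambiguous")
})

test_that("extract_features dispatches by alphabet with consistent rows", {
  set.seed(403)
  prot <- make_sequence_family(10, alphabet = "protein",
                               length_law = list("unif", 30, 60))
  fm <- extract_features(prot, feature_spec(pseaa_lambda = 4))
  expect_equal(dim(fm), c(10L, 24L))
  expect_equal(unname(fm[3, ]),
               unname(pseudo_aa(prot$sequences[[3]], lambda = 4)))

  dna <- toy_dna_family(8)
  spec <- feature_spec(dinuc = c("twist", "roll"), gc = TRUE)
  fd <- extract_features(dna, spec)
  expect_equal(colnames(fd), c("twist", "roll", "gc"))
  expect_equal(unname(fd[1, "gc"]), gc_content(dna$sequences[[1]]))

  expect_error(extract_features(dna, feature_spec(pseaa_lambda = 4)),
               "protein")
  expect_error(extract_features(prot, spec), "nucleotide")
  expect_error(feature_spec(), "empty feature specification")
})
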