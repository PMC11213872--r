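# MS2 spectra I/O, modified-cosine similarity, molecular networking.

make_spec <- function(id, pmz, mz, inten) {
  ms2_spectrum(id, pmz, mz, inten)
}

test_that("MGF and MSP files round-trip losslessly", {
  set.seed(4)
  specs <- list(
    make_spec("a", 163.123, c(80.0494, 106.0651, 132.0808),
              c(100, 55, 20)),
    make_spec("b", 177.1022, c(80.0494, 98.06, 146.0964), c(10, 100, 60)))
  for (fmt in c("mgf", "msp")) {
    path <- file.path(withr::local_tempdir(), paste0("x.", fmt))
    write_spectra(specs, path)
    back <- read_spectra(path)
    expect_length(back, 2L)
    for (i in 1:2) {
      expect_equal(back[[i]]$id, specs[[i]]$id)
      expect_equal(back[[i]]$precursor_mz, specs[[i]]$precursor_mz,
                   tolerance = 1e-5)
      expect_equal(back[[i]]$mz, specs[[i]]$mz, tolerance = 1e-5)
      expect_equal(back[[i]]$intensity, specs[[i]]$intensity,
                   tolerance = 1e-4)
    }
    # read-write-read is the identity on the parsed representation
    path2 <- file.path(withr::local_tempdir(), paste0("y.", fmt))
    write_spectra(back, path2)
    again <- read_spectra(path2)
    expect_equal(again, back)
  }
})

test_that("records without a precursor are skipped with a warning", {
  path <- file.path(withr::local_tempdir(), "bad.msp")
  writeLines(c("Name: good", "PrecursorMZ: 163.123", "Num Peaks: 1",
               "80.05 100", "",
               "Name: broken", "Num Peaks: 1", "80.05 100", ""), path)
  expect_warning(specs <- read_spectra(path), "PrecursorMZ")
  expect_length(specs, 1L)
  expect_equal(specs[[1]]$id, "good")

  mgf <- file.path(withr::local_tempdir(), "bad.mgf")
  writeLines(c("BEGIN IONS", "TITLE=nope", "80.05 100", "END IONS"), mgf)
  expect_warning(specs2 <- read_spectra(mgf), "PEPMASS")
  expect_length(specs2, 0L)
})

test_that("spectrum construction enforces the isotope guard and sorting", {
  expect_error(ms2_spectrum("x", 100, c(50, 102), c(1, 1)), "isotope")
  s <- ms2_spectrum("x", 300, c(200, 100, 150), c(10, 100, 50))
  expect_equal(s$mz, c(100, 150, 200))
  expect_equal(s$intensity, c(100, 50, 10))  # rescaled to base peak 100
})

test_that("similarity is 100 on identity, 0 on disjoint spectra", {
  a <- make_spec("a", 200, c(60, 90, 120), c(100, 50, 25))
  expect_equal(spectral_similarity(a, a)$score, 100, tolerance = 1e-9)
  expect_equal(spectral_similarity(a, a)$matches, 3L)
  b <- make_spec("b", 200, c(61, 91.5, 123), c(100, 50, 25))
  res <- spectral_similarity(a, b)
  expect_equal(res$score, 0)
  expect_equal(res$matches, 0L)
})

test_that("similarity equals the hand-computed cosine on matched pairs", {
  # direct matches at 60 and 90; intensities chosen for a pencil-and-paper
  # cosine: a = (100, 40, 20), b = (80, 60, 50) matched on first two
  a <- make_spec("a", 200, c(60, 90, 130), c(100, 40, 20))
  b <- make_spec("b", 200, c(60.001, 90.002, 150), c(80, 60, 50))
  res <- spectral_similarity(a, b, frag_tol = 0.0025)
  num <- 100 * 80 + 40 * 60
  den <- sqrt(100^2 + 40^2 + 20^2) * sqrt(80^2 + 60^2 + 50^2)
  expect_equal(res$score, 100 * num / den, tolerance = 1e-9)
  expect_equal(res$matches, 2L)
  # coverage: a is the less intense spectrum (sum 160 < 190)
  expect_equal(res$coverage, 100 * (100 + 40) / 160, tolerance = 1e-9)
})

test_that("precursor-shifted fragments are matched (modified cosine)", {
  # b is a +16 Da product whose fragments all shift with the precursor
  a <- make_spec("a", 163.123, c(80.05, 106.065, 132.081), c(100, 60, 30))
  b <- make_spec("b", 179.118, c(80.05, 106.065, 132.081) +
                   (179.118 - 163.123), c(100, 60, 30))
  res <- spectral_similarity(a, b)
  expect_equal(res$score, 100, tolerance = 1e-9)
  expect_equal(res$matches, 3L)
})

test_that("similarity is symmetric and empty spectra warn with score 0", {
  set.seed(8)
  for (i in 1:10) {
    a <- make_spec("a", runif(1, 150, 400),
                   sort(runif(6, 50, 140)), runif(6, 1, 100))
    b <- make_spec("b", runif(1, 150, 400),
                   sort(runif(7, 50, 140)), runif(7, 1, 100))
    expect_identical(spectral_similarity(a, b)$score,
                     spectral_similarity(b, a)$score)
  }
  e <- make_spec("e", 100, numeric(0), numeric(0))
  a <- make_spec("a", 100, 50, 100)
  expect_warning(res <- spectral_similarity(a, e), "empty")
  expect_equal(res$score, 0)
})

test_that("network edges honor the threshold conjunction", {
  a <- make_spec("a", 200, c(60, 90), c(100, 90))
  b <- make_spec("b", 200, c(60, 90, 120, 140), c(100, 90, 2, 2))
  # high cosine but only 2 shared peaks -> min_fragments = 3 blocks it
  expect_gt(spectral_similarity(a, b)$score, 90)
  net <- build_network(list(a, b), min_fragments = 3)
  expect_equal(nrow(net$edges), 0L)
  net2 <- build_network(list(a, b), min_fragments = 2)
  expect_equal(nrow(net2$edges), 1L)
})

test_that("a synthetic scaffold family forms one component, decoys none", {
  sim <- generate_feature_table(study_design(n_features = 30, seed = 3))
  sim <- spike_biotransformation_series(sim, seed = 3)
  fam <- sim$truth
  fam$spiked <- fam$spiked[fam$spiked$label %in% c("2", "4", "5c", "6"), ]
  specs <- generate_spectra(fam, n_decoys = 4, seed = 3)
  net <- build_network(specs)
  comp_of <- net$nodes$component[match(c("parent", fam$spiked$feature_id),
                                       net$nodes$id)]
  expect_equal(length(unique(comp_of)), 1L)  # one 5-node family
  expect_equal(sum(net$nodes$component == comp_of[1]), 5L)
  decoys <- grepl("^decoy", net$nodes$id)
  expect_true(all(table(net$nodes$component[decoys]) == 1))
  # decoys not in the family component
  expect_false(any(net$nodes$component[decoys] == comp_of[1]))
})

test_that("edge sets are invariant to input order and to tightening", {
  sim <- generate_feature_table(study_design(n_features = 20, seed = 5))
  sim <- spike_biotransformation_series(sim, seed = 5)
  fam <- sim$truth
  fam$spiked <- fam$spiked[fam$spiked$label %in% c("2", "4", "5c"), ]
  specs <- generate_spectra(fam, n_decoys = 3, seed = 5)
  n1 <- build_network(specs)
  n2 <- build_network(rev(specs))
  key <- function(e) sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  expect_identical(key(n1$edges), key(n2$edges))
  # tightening any threshold never adds edges
  for (tighter in list(list(min_score = 80), list(min_fragments = 6),
                       list(min_coverage = 95))) {
    nt <- do.call(build_network, c(list(specs), tighter))
    expect_true(all(key(nt$edges) %in% key(n1$edges)))
  }
  # degenerate limit: only identical duplicates connect
  dup <- c(specs[1], specs[1])
  dup[[2]]$id <- "copy"
  nx <- build_network(dup, min_score = 100 - 1e-9, min_fragments = 1,
                      min_coverage = 100 - 1e-9)
  expect_equal(nrow(nx$edges), 1L)
})

test_that("network annotation labels nodes and transformation edges", {
  cand <- enumerate_biotransformations("C10H14N2",
                                       default_transformations(),
                                       max_depth = 2)
  cot <- ion_mz("C10H12N2O", "[M+H]+")
  nic <- ion_mz("C10H14N2", "[M+H]+")
  a <- make_spec("nic", nic, c(80.05, 106.065, 130.065), c(100, 60, 30))
  b <- make_spec("cot", cot, c(80.05, 106.065, 130.065) + (cot - nic),
                 c(100, 60, 30))
  net <- build_network(list(a, b))
  net <- annotate_network_with_candidates(net, cand)
  expect_equal(net$nodes$annotation[net$nodes$id == "cot"], "C10H12N2O")
  expect_equal(net$nodes$annotation[net$nodes$id == "nic"], "C10H14N2")
  # oxidation edge label on a +15.9949 shift
  ox <- make_spec("ox", nic + 15.9949146,
                  c(80.05, 106.065, 130.065) + 15.9949146, c(100, 60, 30))
  net2 <- annotate_network_with_candidates(build_network(list(a, ox)), cand)
  expect_match(net2$edges$transformation[1], "oxidation")
  # no candidates -> unchanged topology, NA labels
  net3 <- annotate_network_with_candidates(build_network(list(a, b)), NULL)
  expect_true(all(is.na(net3$nodes$annotation)))
})
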