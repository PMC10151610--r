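test_that("fixture spaces have the advertised combinatorial sizes", {
  da <- make_diels_alder_space()
  expect_length(da$experiments, choose(6, 2) + 1L) # 15 pairs + cpd self-pair
  px <- make_passerini_space()
  expect_length(enumerate_experiments(px$space, arities = 2), 36L)
  expect_length(enumerate_experiments(px$space, arities = 3), 84L)
  nr <- make_named_reaction_space()
  expect_length(enumerate_experiments(nr$space),
                choose(11, 2) + choose(11, 3) + choose(11, 4))
})

test_that("Diels-Alder planted rules fire exactly as declared", {
  da <- make_diels_alder_space()
  src <- da$outcome_source
  expect_identical(src(c("acid", "base")), 1L)
  expect_identical(src(c("filler1", "filler2")), 0L)
  expect_identical(src(c("cpd", "cpd")), 1L)
  expect_identical(src(c("cpd", "dienophile")), 1L)
  expect_identical(src(c("acid", "cpd")), 0L)
  expect_identical(da$expected$total_properties, 4L)
  expect_identical(da$expected$cyclopentadiene_properties, 2L)
  # unobserved pairs can be masked out
  masked <- make_diels_alder_space(unobserved = "acid+base")
  expect_length(masked$experiments, 15L)
})

test_that("Passerini rules are subset-closed over both arities", {
  px <- make_passerini_space()
  src <- px$outcome_source
  expect_identical(src(c("acid1", "carb1", "iso")), 1L)
  expect_identical(src(c("acid2", "carb2", "iso")), 1L)
  expect_identical(src(c("acid1", "amine2")), 1L)
  expect_identical(src(c("acid1", "amine1", "inert1")), 1L) # via the pair
  expect_identical(src(c("acid1", "carb1")), 0L)
  expect_identical(src(c("carb1", "carb2")), 0L)
  expect_identical(src(c("amine1", "carb1", "iso")), 0L)
})

test_that("the named-reaction source reproduces every tabulated vector", {
  nr <- make_named_reaction_space()
  for (nm in names(nr$table)) {
    row <- nr$table[[nm]]
    expect_identical(paste(nr$outcome_source(row$reagents), collapse = ""),
                     row$vector, label = nm)
  }
  expect_identical(nr$outcome_source(c("10", "12")), integer(8))
})

test_that("bold bits never leak to proper sub-combinations", {
  nr <- make_named_reaction_space()
  for (nm in names(nr$table)) {
    row <- nr$table[[nm]]
    for (k in 2:(length(row$reagents) - 1L)) {
      for (sub in combn(row$reagents, k, simplify = FALSE)) {
        got <- nr$outcome_source(sub)
        expect_identical(got[row$bold], 0L,
                         label = paste(nm, experiment_key(sub)))
      }
    }
  }
})

test_that("outcomes are monotone under reagent addition", {
  nr <- make_named_reaction_space()
  ids <- names(nr$space$compounds)
  set.seed(202)
  for (rep in 1:40) {
    sub <- sample(ids, 3)
    sup <- unique(c(sub, sample(ids, 1)))
    expect_true(all(nr$outcome_source(sub) <= nr$outcome_source(sup)))
  }
})

test_that("simulated logs are faithful, reproducible, and correctly noisy", {
  px <- make_passerini_space()
  clean <- simulate_log(px$space, px$outcome_source)
  expect_identical(nrow(clean$outcomes), 120L)
  manual <- vapply(clean$experiments, px$outcome_source, integer(1))
  expect_identical(as.integer(clean$outcomes), manual)
  s1 <- simulate_log(px$space, px$outcome_source, order = "shuffled",
                     noise = noise_model(0.1, 0.1), seed = 99)
  s2 <- simulate_log(px$space, px$outcome_source, order = "shuffled",
                     noise = noise_model(0.1, 0.1), seed = 99)
  expect_identical(s1$experiments, s2$experiments)
  expect_identical(s1$outcomes, s2$outcomes)
})

test_that("false-positive flips concentrate at their nominal rate", {
  sp <- tiny_space(15)
  wide_zero <- function(ids) integer(100) # 105 pairs x 100 bits
  log <- simulate_log(sp, wide_zero, noise = list(eps_fp = 0.5, eps_fn = 0),
                      seed = 31)
  frac <- mean(log$outcomes)
  expect_lt(abs(frac - 0.5), 0.02)
})

test_that("the chromatogram vectorizer flags only genuinely new peaks", {
  bins <- default_bins(c(0, 8), 8)
  r1 <- peak_list(c(1.2, 3.4), c(0.8, 0.6))
  r2 <- peak_list(c(5.05), c(1))
  same <- peak_list(c(1.2, 3.4, 5.05), c(0.5, 0.5, 0.5))
  expect_identical(reactivity_vector_from_chromatograms(list(r1, r2), same,
                                                        bins),
                   integer(8))
  novel <- peak_list(c(1.2, 6.5), c(0.5, 0.9))
  expect_identical(paste(reactivity_vector_from_chromatograms(
    list(r1, r2), novel, bins), collapse = ""), "00000010")
  expect_identical(reactivity_vector_from_chromatograms(list(r1), peak_list(
    numeric(0)), bins), integer(8))
  # peaks outside the window are ignored
  outside <- peak_list(c(9.5), c(1))
  expect_identical(reactivity_vector_from_chromatograms(list(r1), outside,
                                                        bins), integer(8))
})

test_that("augmenting the reference with matched product peaks zeroes the vector", {
  bins <- default_bins(c(0, 8), 8)
  set.seed(17)
  reactants <- list(peak_list(sort(runif(4, 0, 8))))
  product <- peak_list(sort(c(reactants[[1]]$rt[1:2], 2.22, 6.66)))
  v <- reactivity_vector_from_chromatograms(reactants, product, bins)
  expect_gt(sum(v), 0)
  augmented <- list(peak_list(sort(unique(c(reactants[[1]]$rt, product$rt)))))
  expect_identical(reactivity_vector_from_chromatograms(augmented, product,
                                                        bins), integer(8))
})

test_that("peak lists validate their invariants", {
  expect_error(peak_list(c(2, 1)), "increasing")
  expect_error(peak_list(c(-1, 2)))
  expect_error(peak_list(1, intensity = 0))
})

test_that("fingerprints separate the Passerini fixture's planted classes", {
  skip_if_not_installed("ChemmineOB")
  px <- make_passerini_space()
  fb <- fingerprint_basis(px$space, fingerprint_scheme("morgan", 2))
  iso_bits <- fb$compound_bits[["iso"]]
  other_bits <- unique(unlist(fb$compound_bits[
    setdiff(names(fb$compound_bits), "iso")]))
  expect_gt(length(setdiff(iso_bits, other_bits)), 0L)
  acid_shared <- intersect(fb$compound_bits[["acid1"]],
                           fb$compound_bits[["acid2"]])
  inert_bits <- unique(unlist(fb$compound_bits[c("inert1", "inert2")]))
  expect_gt(length(setdiff(acid_shared, inert_bits)), 0L)
})
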