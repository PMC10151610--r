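test_that("registration is idempotent and content-addressed", {
  reg <- theory_registry()
  a <- toy_theory()
  r1 <- register_theory(reg, a)
  r2 <- register_theory(reg, a)
  expect_identical(r1$identifier, r2$identifier)
  expect_match(r1$identifier, "^th-[0-9a-f]{32}$")
  b <- toy_theory(K = 2)
  rb <- register_theory(reg, b, parent = r1$identifier)
  expect_false(rb$identifier == r1$identifier)
  expect_identical(rb$parent, r1$identifier)
  expect_error(register_theory(reg, toy_theory(K = 3), parent = "th-missing"),
               "reference error")
})

test_that("identifiers are stable for a frozen definition", {
  th <- reactivity_theory(
    chemical_space(list(compound("a"), compound("b")), arities = 2),
    K = 2, width = 1, label = "frozen")
  expect_identical(theory_identifier(th),
                   "th-30ccaba39ef04286b147c62732201eb2")
})

test_that("registries persist records as JSON files", {
  dir <- tempfile()
  reg <- theory_registry(dir)
  rec <- register_theory(reg, toy_theory())
  expect_true(file.exists(file.path(dir, paste0(rec$identifier, ".json"))))
  reg2 <- theory_registry(dir)
  expect_identical(names(reg2$records), rec$identifier)
})

test_that("structurally identical theories split the mixture weight evenly", {
  sp <- tiny_space(3)
  a <- reactivity_theory(sp, K = 1, width = 1, label = "a")
  b <- reactivity_theory(sp, K = 1, width = 1, label = "b")
  log <- observation_log(list(c("c1", "c2"), c("c1", "c3"), c("c2", "c3")),
                         matrix(c(1L, 0L, 0L), 3))
  cmp <- compare_theories(a, b, log, quick_config(seed = 44, warmup = 400,
                                                  draws = 400))
  se <- sd(cmp$weight_draws) / sqrt(max(cmp$ess_w, 4))
  expect_lt(abs(cmp$weight_mean - 0.5), 3 * se + 0.02)
})

test_that("an empty log leaves the mixture weight at its Beta(1,1) prior", {
  sp <- tiny_space(3)
  a <- reactivity_theory(sp, K = 1, width = 1, label = "a")
  b <- reactivity_theory(sp, K = 1, width = 1, label = "b")
  empty <- observation_log(list(), matrix(integer(0), 0, 1))
  cmp <- compare_theories(a, b, empty, quick_config(seed = 45, warmup = 300,
                                                    draws = 400))
  expect_lt(abs(mean(cmp$weight_draws) - 0.5), 0.05)
  expect_lt(abs(sd(cmp$weight_draws) - sqrt(1 / 12)), 0.05)
})

test_that("swapping the theories mirrors the mixture weight", {
  sp <- tiny_space(3)
  a <- reactivity_theory(sp, K = 1, width = 1, label = "a",
                         priors = prior_config("conservative-v1",
                                               tensor = c(0.5, 20)))
  b <- reactivity_theory(sp, K = 1, width = 1, label = "b")
  log <- observation_log(list(c("c1", "c2"), c("c1", "c3"), c("c2", "c3")),
                         matrix(c(1L, 1L, 1L), 3))
  cfg <- quick_config(seed = 46, warmup = 400, draws = 400)
  ab <- compare_theories(a, b, log, cfg)
  ba <- compare_theories(b, a, log, cfg)
  se <- sqrt(sd(ab$weight_draws)^2 / max(ab$ess_w, 4) +
             sd(ba$weight_draws)^2 / max(ba$ess_w, 4))
  expect_lt(abs(ab$weight_mean - (1 - ba$weight_mean)),
            3 * se + 0.02)
})

test_that("width mismatches are rejected up front", {
  sp <- tiny_space(3)
  a <- reactivity_theory(sp, K = 1, width = 2, label = "a")
  b <- reactivity_theory(sp, K = 1, width = 1, label = "b")
  log <- observation_log(list(c("c1", "c2")), matrix(1L, 1, 1))
  expect_error(compare_theories(a, b, log, quick_config(seed = 1)),
               "shape error")
})

test_that("thermometer recoding cumulates set-bit counts", {
  log <- observation_log(list(c("a", "b"), c("a", "c"), c("b", "c")),
                         rbind(c(0L, 1L, 0L, 1L), c(0L, 0L, 0L, 0L),
                               c(1L, 1L, 1L, 1L)))
  rec <- thermometer_recode(log)
  expect_identical(rec$outcomes,
                   rbind(c(1L, 1L, 0L, 0L), c(0L, 0L, 0L, 0L),
                         c(1L, 1L, 1L, 1L)))
})

test_that("reinterpretation matches a direct surprise trace and isolates errors", {
  sp <- tiny_space(3)
  th <- reactivity_theory(sp, K = 1, width = 1, label = "plain",
                          priors = "uniform")
  bad <- reactivity_theory(sp, K = 1, width = 4, label = "too-wide")
  log <- observation_log(list(c("c1", "c2"), c("c2", "c3")),
                         matrix(c(1L, 0L), 2))
  cfg <- quick_config(seed = 50, warmup = 250, draws = 200)
  reg <- theory_registry()
  recs <- list(register_theory(reg, th), register_theory(reg, bad))
  rep <- reinterpret(log, recs, cfg)
  direct <- surprise_trace(th, log, cfg, components = c("prior", "final"))
  got <- rep[[theory_identifier(th)]]
  expect_equal(got$trace$a_priori, direct$a_priori)
  expect_equal(got$trace$a_posteriori, direct$a_posteriori)
  expect_identical(nrow(got$anomalies), 0L)
  expect_match(rep[[theory_identifier(bad)]]$error, "width")
})

test_that("count-coded theories see the thermometer-recoded log", {
  sp <- tiny_space(3, arities = 2)
  loc <- reactivity_theory(sp, K = 1, width = 2, label = "location")
  cnt <- reactivity_theory(sp, K = 1, width = 2, label = "count",
                           outcome_coding = "count")
  log <- observation_log(list(c("c1", "c2"), c("c1", "c3")),
                         rbind(c(0L, 1L), c(0L, 0L)))
  cfg <- quick_config(seed = 51, warmup = 250, draws = 200)
  reg <- theory_registry()
  recs <- list(register_theory(reg, loc), register_theory(reg, cnt))
  rep <- reinterpret(log, recs, cfg)
  expect_identical(rep[[theory_identifier(loc)]]$trace$outcome[1], "01")
  expect_identical(rep[[theory_identifier(cnt)]]$trace$outcome[1], "10")
})
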