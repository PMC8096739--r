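# t tests, ANOVA, Bonferroni alphas, and the two-stage gated question
# framework.

test_that("one-sample t matches the closed form and handles edge cases", {
  r <- one_sample_t(c(1, 2, 3), tail = "greater")
  expect_equal(r$statistic, sqrt(3) * 2 / 1, tolerance = 1e-6) # mean/(sd/sqrt(n))
  expect_equal(r$statistic, 3.4641, tolerance = 1e-4)
  expect_equal(r$df, 2)
  # symmetric values around zero: t = 0, one-tailed p = 0.5
  r0 <- one_sample_t(c(-2, -1, 1, 2), tail = "greater")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 0.5)
  expect_warning(rz <- one_sample_t(c(2, 2, 2), tail = "greater"),
                 "zero variance")
  expect_equal(rz$p, 0)
  expect_error(one_sample_t(1), "2 values")
})

test_that("one-tailed p values match numerical integration of the t density", {
  set.seed(12)
  for (n in c(5, 10, 19, 29)) {
    x <- rnorm(n, 0.4)
    r <- one_sample_t(x, tail = "greater")
    expect_equal(r$p, p_upper_t_oracle(r$statistic, r$df), tolerance = 1e-6)
  }
})

test_that("paired and two-sample t tests behave canonically", {
  expect_warning(r_ident <- paired_t(c(1, 2, 3), c(1, 2, 3),
                                     tail = "two.sided"), "zero variance")
  expect_equal(r_ident$statistic, 0)
  r <- two_sample_t(c(0, 1), c(2, 3), tail = "two.sided")
  expect_equal(r$statistic, -2.828427, tolerance = 1e-6)
  expect_equal(r$df, 2)
  # antisymmetry under group exchange
  a <- rnorm(8); b <- rnorm(8)
  expect_equal(two_sample_t(a, b, tail = "two.sided")$statistic,
               -two_sample_t(b, a, tail = "two.sided")$statistic)
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
  expect_error(paired_t(1:3, 1:4), "equal length")
})

test_that("one-way ANOVA matches hand computation and the t^2 identity", {
  r <- one_way_anova(list(c(0, 1), c(2, 3)))
  expect_equal(r$statistic, 8)
  expect_equal(c(r$df, r$df2), c(1, 2))
  # equal group means: F ~ 0
  expect_lt(one_way_anova(list(c(1, 2, 3), c(3, 2, 1)))$statistic, 1e-10)
  # with k = 2 groups, F equals the squared pooled t
  set.seed(13)
  a <- rnorm(6); b <- rnorm(7) + 0.5
  expect_equal(one_way_anova(list(a, b))$statistic,
               two_sample_t(a, b, tail = "two.sided")$statistic^2,
               tolerance = 1e-10)
  expect_error(one_way_anova(list(c(1, 2))), ">= 2 groups")
})

test_that("seed-level Bonferroni alphas reproduce the published thresholds", {
  expect_equal(bonferroni_alpha(0.05, 8), 0.00625)
  expect_equal(bonferroni_alpha(0.05, 12), 0.05 / 12)
  expect_equal(round(bonferroni_alpha(0.05, 12), 5), 0.00417)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  # strictly decreasing in the region count
  alphas <- sapply(1:12, bonferroni_alpha, base_alpha = 0.05)
  expect_true(all(diff(alphas) < 0))
  expect_error(bonferroni_alpha(0.05, 0), ">= 1")
})

test_that("the packaged question specs encode the published alpha policy", {
  specs <- load_question_specs()
  expect_setequal(names(specs), c("q1a", "q1b", "q2a", "q2b", "q3a", "q3b",
                                  "q3c"))
  gate_div <- sapply(specs, function(s) s$gate_alpha$divisor)
  expect_equal(gate_div[c("q1a", "q1b", "q3c")], c(12, 12, 12),
               ignore_attr = TRUE)
  expect_equal(gate_div[c("q2a", "q2b", "q3a", "q3b")], c(8, 8, 8, 8),
               ignore_attr = TRUE)
  # second-level thresholds: 0.0056, 0.0125, 0.0083, 0.025, 0.016, 0.05
  fu_alpha <- function(q, name) {
    fu <- Filter(function(f) f$name == name, specs[[q]]$followups)[[1]]
    bonferroni_alpha(fu$alpha$base, fu$alpha$divisor)
  }
  expect_equal(round(fu_alpha("q1a", "perception_gt_imagery"), 4), 0.0056)
  expect_equal(fu_alpha("q1b", "faces_gt_buildings_face_areas"), 0.0125)
  expect_equal(round(fu_alpha("q1b", "buildings_gt_faces_scene_areas"), 4),
               0.0083)
  expect_equal(fu_alpha("q2a", "city_diff_gt_same"), 0.025)
  expect_equal(round(fu_alpha("q2b", "perc_gt_imag_diff_quadrant"), 3), 0.017)
  expect_equal(fu_alpha("q3c", "perc_gt_imag_buildings"), 0.05)
  expect_equal(fu_alpha("q3c", "perc_buildings_gt_faces"), 0.025)
  # region sets are hemisphere-resolved
  expect_length(specs$q1a$regions, 12)
  expect_length(specs$q2a$regions, 8)
})

make_fixture_distances <- function(regions, selections, n = 10,
                                   shift = function(reg, sel) 0, sd = 1,
                                   seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(regions, function(reg)
    do.call(rbind, lapply(selections, function(sel)
      data.frame(subject = sprintf("s%02d", 1:n), region = reg,
                 selection = sel,
                 value = rnorm(n, shift(reg, sel), sd),
                 stringsAsFactors = FALSE)))))
}

test_that("gating: no surviving region leaves stage 2 empty", {
  spec <- question_spec(
    "toy", selections = list(sel_a = cell_selection(), sel_b = cell_selection()),
    gates = c("sel_a", "sel_b"),
    gate_alpha = list(base = 0.05, divisor = NULL),
    followups = list(list(name = "f", type = "paired_t", a = "sel_a",
                          b = "sel_b", tail = "greater",
                          requires = c("sel_a", "sel_b"),
                          alpha = list(base = 0.05, divisor = NULL))))
  d <- make_fixture_distances(c("R1", "R2"), c("sel_a", "sel_b"),
                              shift = function(r, s) 0, seed = 2)
  res <- run_question(spec, d)
  expect_null(res$followups)
  expect_length(res$eligible$f, 0)
  expect_equal(res$gate_alpha, 0.025) # divisor defaults to region count
})

test_that("eligibility admits exactly the regions passing all required gates", {
  spec <- question_spec(
    "toy", selections = list(sel_a = cell_selection(), sel_b = cell_selection()),
    gates = c("sel_a", "sel_b"),
    gate_alpha = list(base = 0.05, divisor = 4),
    followups = list(list(name = "f", type = "paired_t", a = "sel_a",
                          b = "sel_b", tail = "greater",
                          requires = c("sel_a", "sel_b"),
                          alpha = list(base = 0.05, divisor = NULL))))
  # R1: both gates strong; R2: only sel_a; R3: nothing
  sh <- function(reg, sel) {
    if (reg == "R1") 3 else if (reg == "R2" && sel == "sel_a") 3 else 0
  }
  d <- make_fixture_distances(c("R1", "R2", "R3"), c("sel_a", "sel_b"),
                              n = 12, shift = sh, sd = 1, seed = 3)
  res <- run_question(spec, d)
  expect_equal(res$eligible$f, "R1")
  expect_equal(res$followups$region, "R1")
  expect_equal(unique(res$followups$alpha), 0.05) # 0.05 / 1 eligible region
  # gate discipline: no stage-2 rows outside the eligible set
  expect_true(all(res$followups$region %in% res$eligible$f))
})

test_that("Q1a runs two gates per region and paired follow-ups on survivors", {
  spec <- load_question_specs()$q1a
  regions <- spec$regions
  sh <- function(reg, sel) if (reg %in% c("FFA_LH", "PPA_RH")) {
    if (sel == "cross_category_perception") 4 else 2.5
  } else 0
  d <- make_fixture_distances(regions, spec$gates, n = 19, shift = sh,
                              seed = 4)
  res <- run_question(spec, d)
  # exactly two one-sample tests per region (one per domain)
  expect_equal(nrow(res$gates), 2 * length(regions))
  expect_equal(res$gate_alpha, 0.05 / 12)
  expect_setequal(res$eligible$perception_gt_imagery, c("FFA_LH", "PPA_RH"))
  expect_equal(unique(res$followups$alpha), 0.05 / 9)
  expect_true(all(res$followups$test == "paired_t"))
})

test_that("auto_group picks a two-sample t for two groups, ANOVA for three", {
  spec <- question_spec(
    "toy3",
    selections = list(g1 = cell_selection(), g2 = cell_selection(),
                      g3 = cell_selection()),
    gates = c("g1", "g2", "g3"),
    gate_alpha = list(base = 0.05, divisor = 8),
    followups = list(list(name = "cmp", type = "auto_group",
                          groups = c("g1", "g2", "g3"), tail = "greater",
                          requires = c("g1", "g2", "g3"), min_required = 2,
                          alpha = list(base = 0.05, divisor = 1))))
  sh <- function(reg, sel) {
    if (reg == "R2") 3 # all three significant -> ANOVA
    else if (reg == "R1" && sel != "g3") 3 # two significant -> two-sample t
    else 0
  }
  d <- make_fixture_distances(c("R1", "R2"), c("g1", "g2", "g3"), n = 15,
                              shift = sh, seed = 5)
  res <- run_question(spec, d)
  expect_setequal(res$eligible$cmp, c("R1", "R2"))
  tests <- setNames(res$followups$test, res$followups$region)
  expect_equal(tests[["R1"]], "two_sample_t")
  expect_equal(tests[["R2"]], "one_way_anova")
})

test_that("run_question validates its inputs", {
  spec <- question_spec("toy", selections = list(s = cell_selection()),
                        gates = "s")
  d <- make_fixture_distances("R1", "s")
  expect_error(run_question(spec, d[, 1:3]), "columns")
  spec2 <- question_spec("toy", selections = list(s = cell_selection()),
                         gates = "s", regions = c("R1", "R9"))
  expect_error(run_question(spec2, d), "lack region")
  expect_error(
    question_spec("bad", selections = list(s = cell_selection()),
                  gates = "s",
                  followups = list(list(name = "f", type = "paired_t",
                                        requires = "zzz"))),
    "non-gated")
})
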