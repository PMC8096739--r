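# Cell selection, outlier exclusion, within-subject averaging, and subject
# merging.

`%||ct%` <- function(a, b) if (is.null(a)) b else a

test_that("select_pairs equals brute-force filtering for many predicates", {
  cases <- list(
    list(conds = make_stimulus_set(1), category = "same", quadrant = "same"),
    list(conds = make_stimulus_set(1), category = "same",
         quadrant = "different", restrict = list(category = "city")),
    list(conds = make_stimulus_set(2), domain = "different",
         category = "same"),
    list(conds = make_stimulus_set(3), category = "different",
         domain = "same", restrict = list(domain = "perception")),
    list(conds = make_stimulus_set(3), category = "same", domain = "same",
         restrict = list(category = "face", domain = "imagery")))
  for (cs in cases) {
    sel <- cell_selection(category = cs$category %||ct% "ignore",
                          domain = cs$domain %||ct% "ignore",
                          quadrant = cs$quadrant %||ct% "ignore",
                          restrict = cs$restrict %||ct% list())
    got <- select_pairs(cs$conds, sel)
    oracle <- brute_force_pairs(cs$conds,
                                category = cs$category %||ct% "ignore",
                                domain = cs$domain %||ct% "ignore",
                                quadrant = cs$quadrant %||ct% "ignore",
                                restrict = cs$restrict %||ct% list())
    expect_equal(unname(as.matrix(got)), unname(oracle))
  }
})

test_that("pair taxonomies match the experiments' combinatorics", {
  b1 <- make_stimulus_set(1)
  b1 <- b1[b1$category == "building", ]
  expect_equal(nrow(select_pairs(b1, cell_selection(quadrant = "same"))), 4)
  expect_equal(nrow(select_pairs(b1, cell_selection(quadrant = "different"))),
               24)
  c3 <- make_stimulus_set(3)
  expect_equal(nrow(select_pairs(c3, cell_selection(
    category = "different", domain = "same",
    restrict = list(domain = "perception")))), 36)
  # within-category within-domain item pairs of Experiment 3: C(6,2)
  expect_equal(nrow(select_pairs(c3, cell_selection(
    category = "same", domain = "same",
    restrict = list(category = "building", domain = "perception")))), 15)
  # cross-domain building pairs of Experiment 3 (same-item pairs included)
  expect_equal(nrow(select_pairs(c3, cell_selection(
    category = "same", domain = "different",
    restrict = list(category = "building")))), 36)
})

test_that("diagonal cells are never selected and absent factors error", {
  c3 <- make_stimulus_set(3)
  sel <- cell_selection() # everything ignored: all off-diagonal pairs
  pairs <- select_pairs(c3, sel)
  expect_equal(nrow(pairs), choose(nrow(c3), 2))
  expect_true(all(pairs$i < pairs$j))
  expect_error(select_pairs(c3, cell_selection(quadrant = "same")),
               "absent")
})

test_that("the 2 SD exclusion rule pools, masks strictly, keeps boundaries", {
  # all equal: SD 0, nothing excluded
  expect_true(all(exclude_outliers(rep(3, 8))))
  # one extreme value among ten: mean 10, SD ~31.6, 100 > 10 + 2 SD
  v <- c(rep(0, 9), 100)
  expect_equal(which(!exclude_outliers(v)), 10L)
  # masking is strictly-beyond-2-SD: a value just inside the boundary is
  # retained, just outside it is excluded (boundary solved numerically)
  base <- c(-2, -1, 0, 1, 2)
  zfun <- function(t) {
    x <- c(base, t)
    (t - mean(x)) / stats::sd(x) - 2
  }
  t_star <- stats::uniroot(zfun, c(3, 50), tol = 1e-12)$root
  expect_true(exclude_outliers(c(base, t_star * (1 - 1e-6)))[6])
  expect_false(exclude_outliers(c(base, t_star * (1 + 1e-3)))[6])
  # grouping: exclusion is computed within groups
  g <- rep(1:2, each = 10)
  vals <- c(v, rep(5, 10))
  keep <- exclude_outliers(vals, g)
  expect_equal(sum(!keep), 1L)
  expect_error(exclude_outliers(c(1), c(1)), "fewer than 2")
})

test_that("average_cells averages exactly the unmasked selected cells", {
  conds <- make_stimulus_set(1)[1:6, ]
  d <- matrix(0, 6, 6)
  d[upper.tri(d)] <- 1:15
  d <- d + t(d)
  rdm <- crossnobis:::new_rdm(d, conds)
  pairs <- data.frame(i = c(1, 2, 3, 4), j = c(2, 3, 4, 5))
  expect_equal(average_cells(rdm, pairs[1, ]), d[1, 2])
  expect_equal(average_cells(rdm, pairs),
               mean(d[cbind(pairs$i, pairs$j)]))
  mask <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(average_cells(rdm, pairs, mask),
               mean(c(d[1, 2], d[3, 4])))
  expect_warning(val <- average_cells(rdm, pairs, rep(FALSE, 4)), "excluded")
  expect_true(is.na(val))
  expect_error(average_cells(rdm, pairs[0, ]), "empty")
})

test_that("block-structured RDMs average in the built-in order", {
  conds <- make_stimulus_set(3)
  g <- make_geometry(conds, c(category = 2, item = 0.2), n_voxels = 30,
                     seed = 11)
  rdm <- true_rdm(g)
  between <- average_cells(rdm, select_pairs(conds, cell_selection(
    category = "different", domain = "same",
    restrict = list(domain = "imagery"))))
  within <- average_cells(rdm, select_pairs(conds, cell_selection(
    category = "same", domain = "same",
    restrict = list(domain = "imagery"))))
  expect_gt(between, within)
})

test_that("subject_distances masks before averaging, per selection", {
  conds <- toy_conditions(c("a", "b", "c"))
  sel <- list(all_pairs = cell_selection())
  mk <- function(vals) {
    d <- matrix(0, 3, 3)
    d[upper.tri(d)] <- vals
    crossnobis:::new_rdm(d + t(d), conds)
  }
  # 2 subjects x 3 pairs; one wild value in subject 2
  rdms <- list(s1 = list(R = mk(c(1, 2, 3))),
               s2 = list(R = mk(c(2, 3, 1000))))
  out <- subject_distances(rdms, sel, conds, exclude_k = 2)
  expect_equal(nrow(out), 2)
  pooled <- c(1, 2, 2, 3, 3, 1000)
  keep <- abs(pooled - mean(pooled)) <= 2 * stats::sd(pooled)
  expect_equal(out$value[out$subject == "s1"], mean(c(1, 2, 3)))
  expect_equal(out$value[out$subject == "s2"], mean(c(2, 3)))
  expect_equal(out$n_excluded[out$subject == "s2"], 1L)
  # with the rule disabled the wild value stays in
  out2 <- subject_distances(rdms, sel, conds, exclude_k = NULL)
  expect_equal(out2$value[out2$subject == "s2"], mean(c(2, 3, 1000)))
})

test_that("repeat subjects merge by averaging across experiments", {
  e1 <- data.frame(subject = sprintf("s%02d", 1:15), value = 10)
  e2 <- data.frame(subject = c("s01", "s02", sprintf("t%02d", 1:14)),
                   value = 20)
  merged <- merge_repeat_subjects(list(e1, e2))
  expect_equal(nrow(merged), 29) # 15 + 16 - 2 overlap
  expect_equal(merged$value[merged$subject == "s01"], 15)
  expect_equal(merged$value[merged$subject == "s05"], 10)
  expect_equal(merged$value[merged$subject == "t01"], 20)
  expect_error(merge_repeat_subjects(list(rbind(e1, e1[1, ]))), "duplicated")
})
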