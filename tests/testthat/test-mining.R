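test_that("peripheral classification uses normalised nucleus-edge depth", {
  nuc <- circle_poly(c(0, 0), 10)
  cell <- circle_poly(c(0, 0), 20)
  # backbone sitting at r = 19.5: depth 0.95 -> peripheral
  bb <- circle_poly(c(0, 0), 19.5, n = 16L)[1:8, ]
  res <- classify_peripheral(bb, nuc, cell)
  expect_true(res$peripheral)
  expect_equal(res$depth, 0.95, tolerance = 0.01)
  # near the nuclear envelope: depth ~ 0 -> perinuclear
  bb0 <- circle_poly(c(0, 0), 10.05, n = 16L)[1:8, ]
  res0 <- classify_peripheral(bb0, nuc, cell)
  expect_false(res0$peripheral)
  expect_lt(res0$depth, 0.05)
  # just inside the cell edge: depth ~ 1
  bb1 <- circle_poly(c(0, 0), 19.99, n = 16L)[1:8, ]
  expect_gt(classify_peripheral(bb1, nuc, cell)$depth, 0.99)
  # violations are errors
  expect_error(classify_peripheral(rbind(c(25, 0)), nuc, cell), "outside")
  expect_error(classify_peripheral(rbind(c(5, 0)), nuc, cell), "nucleus")
})

test_that("the property matrix encodes presence/absence pairs", {
  res <- data.frame(
    tubule = c("t1", "t2", "t3"),
    sustained_curvature = c(FALSE, TRUE, NA),
    alpha = c(0.3, 0.8, 0.5),
    peripheral = c(TRUE, FALSE, TRUE),
    skew = c(FALSE, TRUE, FALSE))
  expect_warning(pm <- build_property_matrix(res), "excluded")
  expect_equal(nrow(pm), 2L)
  expect_equal(colnames(pm), property_columns())
  # alpha = 0.3, no skew, peripheral, no curvature -> (0,1,0,1,1,0,0,1)
  expect_equal(unname(pm["t1", ]), c(0L, 1L, 0L, 1L, 1L, 0L, 0L, 1L))
  # presence + absence sum to 1 per property
  for (j in c(1L, 3L, 5L, 7L))
    expect_true(all(pm[, j] + pm[, j + 1L] == 1L))
  expect_error(build_property_matrix(res[0L, ]), "no tubules")
})

test_that("rule mining matches hand counts on designed matrices", {
  # A always co-occurs with B; A present in 5 of 10 rows
  m <- cbind(A = c(rep(1L, 5L), rep(0L, 5L)),
             B = c(rep(1L, 5L), 1L, rep(0L, 4L)),
             C = rep(c(1L, 0L), 5L))
  rules <- mine_rules(m, min_support = 0.1, min_confidence = 0.9)
  ab <- rules[rules$antecedent == "A" & rules$consequent == "B", ]
  expect_equal(nrow(ab), 1L)
  expect_equal(ab$support, 0.5)
  expect_equal(ab$confidence, 1.0)
  expect_equal(ab$lift, 0.5 / (0.5 * 0.6))
  # independent balanced items: lift 1 (confidence below 0.9, so lower the
  # threshold to observe it)
  m2 <- cbind(A = rep(c(1L, 1L, 0L, 0L), 3L),
              B = rep(c(1L, 0L, 1L, 0L), 3L))
  r2 <- mine_rules(m2, min_support = 0.1, min_confidence = 0.1)
  expect_true(all(abs(r2$lift - 1) < 1e-12))
  # a 1-in-20 item cannot pair above min_support 0.1
  m3 <- cbind(A = c(1L, rep(0L, 19L)), B = c(0L, rep(1L, 19L)))
  r3 <- mine_rules(m3, min_support = 0.1, min_confidence = 0.5)
  expect_false(any(grepl("A", paste(r3$antecedent, r3$consequent))))
  # threshold validation
  expect_error(mine_rules(m, min_support = 0), "thresholds")
  expect_error(mine_rules(m, min_confidence = 1.2), "thresholds")
  expect_error(mine_rules(m[1:5, ]), "at least 10")
})

test_that("mining agrees with a brute-force enumerator on random matrices", {
  for (seed in 1:100) {
    pm <- random_property_matrix(50L, seed = seed)
    got <- as.data.frame(mine_rules(pm, 0.1, 0.9))
    want <- brute_force_rules(pm, 0.1, 0.9)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      key <- function(d) order(d$antecedent, d$consequent)
      got <- got[key(got), ]; want <- want[key(want), ]
      expect_equal(got$antecedent, want$antecedent)
      expect_equal(got$consequent, want$consequent)
      expect_equal(got$support, want$support, tolerance = 1e-12)
      expect_equal(got$confidence, want$confidence, tolerance = 1e-12)
      expect_equal(got$lift, want$lift, tolerance = 1e-12)
    }
  }
})

test_that("raising thresholds never adds rules", {
  pm <- random_property_matrix(60L, seed = 11L)
  base <- as.data.frame(mine_rules(pm, 0.1, 0.5))
  key <- function(d) paste(d$antecedent, "->", d$consequent)
  for (ms in c(0.2, 0.3)) {
    sub <- as.data.frame(mine_rules(pm, ms, 0.5))
    expect_true(all(key(sub) %in% key(base)))
  }
  for (mc in c(0.7, 0.9)) {
    sub <- as.data.frame(mine_rules(pm, 0.1, mc))
    expect_true(all(key(sub) %in% key(base)))
  }
})

test_that("emitted rule metrics satisfy their defining identities", {
  pm <- random_property_matrix(50L, seed = 77L)
  rules <- mine_rules(pm, 0.05, 0.3)
  m <- unclass(pm)
  supp <- function(items) {
    cols <- match(items, colnames(m))
    mean(rowSums(m[, cols, drop = FALSE]) == length(cols))
  }
  for (i in seq_len(nrow(rules))) {
    a <- strsplit(rules$antecedent[i], " & ", fixed = TRUE)[[1L]]
    b <- strsplit(rules$consequent[i], " & ", fixed = TRUE)[[1L]]
    expect_length(intersect(a, b), 0L)
    expect_equal(rules$support[i], supp(c(a, b)), tolerance = 1e-12)
    expect_equal(rules$confidence[i], supp(c(a, b)) / supp(a),
                 tolerance = 1e-12)
    expect_equal(rules$lift[i], rules$confidence[i] / supp(b),
                 tolerance = 1e-12)
    expect_true(rules$support[i] <= rules$confidence[i])
  }
})
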