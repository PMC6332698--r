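test_that("parameter validation rejects degenerate combinations", {
  expect_s3_class(combination_params(), "combination_params")
  expect_error(combination_params(w_c = -0.1), "non-negative")
  expect_error(combination_params(w_c = 0, w_a = 0), "non-negative")
  expect_error(combination_params(c_scale = 0), "positive")
  expect_error(combination_params(theta_low = 0.8, theta_high = 0.5), "below")
})

test_that("the linear blend floors at zero and is monotone in each term", {
  p <- combination_params()
  expect_equal(combine_terms(0, 0, p), 0)
  # strongly negative composition is clamped at the floor
  expect_equal(combine_terms(-10, 0, p), 0)
  # monotone grid sweep in the amyloid term
  a_grid <- seq(0, 100, by = 5)
  s <- combine_terms(0.02, a_grid, p)
  expect_true(all(diff(s) >= 0))
  # and in the composition term
  c_grid <- seq(-0.1, 0.2, by = 0.01)
  s2 <- combine_terms(c_grid, 50, p)
  expect_true(all(diff(s2) >= 0))
  # default normalisations: c/0.05 and a/100, equal weights
  expect_equal(combine_terms(0.05, 50, p), 0.5 * 1 + 0.5 * 0.5)
})

test_that("classification uses strict low/high thresholds with an inclusive middle band", {
  expect_equal(as.character(classify_score(c(0.44, 0.45, 0.78, 0.79))),
               c("low", "increased", "increased", "high"))
  # published-style values: 0.34 is low, 0.93 is high
  expect_equal(as.character(classify_score(0.34)), "low")
  expect_equal(as.character(classify_score(0.93)), "high")
  # classes partition [0, Inf) exhaustively and exclusively
  set.seed(301)
  s <- c(runif(200, 0, 2), 0.45, 0.78, 0)
  cls <- classify_score(s)
  expect_false(any(is.na(cls)))
  expect_equal(sum(cls == "low") + sum(cls == "increased") + sum(cls == "high"),
               length(s))
})

test_that("compare_sequences preserves order and zeroes the self-delta", {
  set.seed(302)
  ref <- generate_synthetic_prld(100, seed = 11, id = "ref")
  out <- compare_sequences(ref, ref)
  expect_equal(nrow(out), 2L)
  expect_equal(out$delta[2], 0)
  expect_equal(out$role, c("reference", "variant"))

  vars <- dplyr::bind_rows(
    apply_mutation(ref, paste0(substr(ref$sequence, 50, 50), "50I")),
    apply_mutation(ref, paste0(substr(ref$sequence, 60, 60), "60P")),
    ref)
  out1 <- compare_sequences(ref, vars)
  out2 <- compare_sequences(ref, vars[c(3, 1, 2), ])
  expect_equal(out1$id[-1], vars$id)
  # permuting variant input order permutes output rows identically
  expect_equal(out2$score[-1], out1$score[c(4, 2, 3)])
  expect_equal(out1$score - out1$score[1], out1$delta)
  expect_true(all(c("impact") %in% names(out1)))
})

test_that("saturation scan returns 20 deterministic rows consistent with compare mode", {
  wt <- generate_synthetic_prld(90, seed = 12, id = "wt")
  pos <- 45L
  scan <- single_mutation_scan(wt, pos)
  expect_equal(nrow(scan), 20L)
  expect_equal(scan$role[1], "wild_type")
  expect_equal(scan$delta[1], 0)
  wt_res <- substr(wt$sequence, pos, pos)
  expect_equal(scan$substitution[-1],
               paste0(wt_res, pos, setdiff(AA, wt_res)))
  # wild-type row equals the compare-mode self-comparison
  self <- compare_sequences(wt, wt)
  expect_equal(scan$score[1], self$score[2])
  expect_equal(scan$composition[1], self$composition[2])
  # a proline substitution in the scan matches scoring that mutant directly
  mutp <- apply_mutation(wt, tibble::tibble(from = wt_res, position = pos, to = "P"))
  direct <- score_proteins(mutp)
  expect_equal(scan$score[which(scan$substitution == paste0(wt_res, pos, "P"))],
               direct$score)
  expect_error(single_mutation_scan(wt, 91), "outside")
})

test_that("noiseless synthetic anchors are recovered exactly", {
  anch <- dplyr::bind_rows(lapply(1:8, function(i) {
    generate_synthetic_prld(120, seed = i, id = paste0("a", i))
  }))
  truth <- combination_params(w_c = 0.7, w_a = 0.3)
  anch$published <- score_proteins(anch, params = truth)$score
  cal <- calibrate_params(anch)
  expect_equal(cal$params$w_c, 0.7, tolerance = 1e-9)
  expect_equal(cal$params$w_a, 0.3, tolerance = 1e-9)
  g <- glance(cal)
  expect_lt(g$rmse, 1e-9)
  td <- tidy(cal)
  expect_equal(td$term, c("w_c", "w_a"))
})

test_that("single-weight calibration reduces to a closed-form ratio", {
  anch <- dplyr::bind_rows(lapply(1:4, function(i) {
    generate_synthetic_prld(120, seed = 20 + i, id = paste0("b", i))
  }))
  p0 <- combination_params()
  scored <- score_proteins(anch, params = p0)
  anch$published <- scored$score
  cal <- calibrate_params(anch, params = p0, free = "w_a")
  # manual normal equation: w_a = sum(na * (pub - w_c*nc)) / sum(na^2)
  resp <- anch$published - p0$w_c * scored$composition_norm
  manual <- sum(scored$amyloid_norm * resp) / sum(scored$amyloid_norm^2)
  expect_equal(cal$params$w_a, manual, tolerance = 1e-12)
  expect_equal(cal$params$w_c, p0$w_c)
})

test_that("floor-clamped anchors are excluded from the fit but kept in the table", {
  base <- dplyr::bind_rows(lapply(1:6, function(i) {
    generate_synthetic_prld(120, seed = 30 + i, id = paste0("c", i))
  }))
  truth <- combination_params(w_c = 0.7, w_a = 0.3)
  base$published <- score_proteins(base, params = truth)$score
  # force two anchors to the floor (others may sit there naturally)
  base$published[c(2, 5)] <- 0
  cal <- calibrate_params(base)
  expect_equal(cal$anchors$in_fit, base$published > 0)
  expect_false(any(cal$anchors$in_fit[c(2, 5)]))
  expect_equal(nrow(cal$anchors), 6L)
})

test_that("calibration errors on degenerate anchor sets", {
  one <- generate_synthetic_prld(120, seed = 40, id = "only")
  one$published <- 0.5
  expect_error(calibrate_params(one), class = "prionscore_calibration_error")
  same <- dplyr::bind_rows(one, one)
  same$id <- c("x", "y")
  same$published <- c(0.5, 0.5)
  expect_error(calibrate_params(same), class = "prionscore_calibration_error")
})

test_that("calibration under noise concentrates with more anchors", {
  # weight RMSE over replicates shrinks as the anchor count grows
  truth <- combination_params(w_c = 0.6, w_a = 0.4)
  rmse_for <- function(n_anchor, reps, seed0) {
    errs <- vapply(seq_len(reps), function(r) {
      anch <- dplyr::bind_rows(lapply(seq_len(n_anchor), function(i) {
        generate_synthetic_prld(120, seed = seed0 + r * 100 + i,
                                id = paste0("n", i))
      }))
      clean <- score_proteins(anch, params = truth)$score
      anch$published <- clean + withr::with_seed(seed0 + r, rnorm(n_anchor, 0, 0.05))
      anch <- anch[anch$published > 0, ]
      cal <- calibrate_params(anch, params = truth)
      sqrt(mean(c(cal$params$w_c - 0.6, cal$params$w_a - 0.4)^2))
    }, numeric(1))
    sqrt(mean(errs^2))
  }
  few <- rmse_for(5, 8, 5000)
  many <- rmse_for(25, 8, 6000)
  expect_lt(many, few)
})

test_that("predict() scores new records with the calibrated parameters", {
  anch <- dplyr::bind_rows(lapply(1:5, function(i) {
    generate_synthetic_prld(120, seed = 50 + i, id = paste0("p", i))
  }))
  truth <- combination_params(w_c = 0.8, w_a = 0.2)
  anch$published <- score_proteins(anch, params = truth)$score
  cal <- calibrate_params(anch)
  new <- generate_synthetic_prld(100, seed = 99, id = "new")
  expect_equal(predict(cal, new)$score,
               score_proteins(new, params = truth)$score, tolerance = 1e-9)
})
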