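test_that("regression calibration echoes its constants", {
  cal <- icong_calibration(27, mode = "regression", a = 1.5, b = 0.5)
  expect_equal(cal$expected_mast, 1.5 * 27^0.5)
  cal_d <- icong_calibration(27, mode = "regression")
  expect_gt(cal_d$expected_mast, 1)
  expect_lt(cal_d$expected_mast, 27)
  expect_error(icong_calibration(3), ">= 4")
})

test_that("Monte-Carlo calibration is reproducible and stores its null sample", {
  c1 <- icong_calibration(8, mode = "montecarlo", R = 150, seed = 5)
  c2 <- icong_calibration(8, mode = "montecarlo", R = 150, seed = 5)
  expect_identical(c1$null_sizes, c2$null_sizes)
  expect_length(c1$null_sizes, 150)
  expect_equal(c1$expected_mast, mean(c1$null_sizes))
  expect_error(icong_calibration(8, mode = "montecarlo", R = 50), ">= 100")
})

test_that("p decreases in MAST size and is floored above zero", {
  creg <- icong_calibration(20, mode = "regression")
  cmc <- icong_calibration(10, mode = "montecarlo", R = 200, seed = 2)
  for (cal in list(creg, cmc)) {
    ps <- vapply(seq_len(cal$n), function(k) icongr:::icong_p_value(cal, k), 0)
    expect_true(all(diff(ps) <= 0))
    expect_true(all(ps > 0 & ps <= 1))
  }
  # identical trees achieve the calibration floor
  t <- random_tree(10, "yule", seed = 4)
  res <- icong_test(t, t, cmc)
  expect_equal(res$mast, 10L)
  expect_lte(res$p, 1 / (cmc$R + 1) + 1e-12)
  expect_equal(res$icong, 10 / cmc$expected_mast)
})

test_that("icong values lie on the discrete grid k / E", {
  cal <- icong_calibration(12, mode = "regression")
  for (k in c(4, 7, 10)) {
    pair <- make_tree_pair_with_mast(12, k, seed = k)
    res <- icong_test(pair$t1, pair$t2, cal)
    expect_equal(res$mast, k)
    expect_equal(res$icong, k / cal$expected_mast)
  }
})

test_that("congruence_table covers all pairs and rejects mixed leaf sets", {
  cal <- icong_calibration(8, mode = "regression")
  trees <- lapply(1:4, function(s) random_tree(8, "yule", seed = s))
  names(trees) <- paste0("T", 1:4)
  tab <- congruence_table(trees, cal)
  expect_equal(nrow(tab), 6L)  # 4 * 3 / 2
  expect_s3_class(tab, "congruence_table")

  # order of the pair does not matter
  r_ab <- icong_test(trees$T1, trees$T2, cal)
  r_ba <- icong_test(trees$T2, trees$T1, cal)
  expect_equal(r_ab$mast, r_ba$mast)
  expect_equal(r_ab$icong, r_ba$icong)
  expect_equal(r_ab$p, r_ba$p)

  bad <- c(trees, list(T5 = random_tree(8, "yule", seed = 9,
                                        labels = letters[1:8])))
  expect_error(congruence_table(bad, cal), "mixed leaf sets")
  expect_error(icong_test(trees$T1, random_tree(9, "yule", seed = 1),
                          cal), "leaf sets")
})

test_that("fit_icong_grid recovers a known unit", {
  E_true <- 7.3
  vals <- round((5:11) / E_true, 2)
  fit <- fit_icong_grid(vals)
  expect_equal(fit$k, 5:11)
  expect_lt(abs(fit$E - E_true), 0.05)
})

test_that("reports render the Icong; p cells with significance flags", {
  cal <- icong_calibration(8, mode = "regression")
  trees <- lapply(1:3, function(s) random_tree(8, "yule", seed = s + 20))
  names(trees) <- c("reference", "whole_genome", "cell_wall")
  tab <- congruence_table(trees, cal)
  tsv <- tempfile(fileext = ".tsv"); md <- tempfile(fileext = ".md")
  write_congruence_report(tab, tsv, md)
  re <- utils::read.delim(tsv)
  expect_equal(nrow(re), 3L)
  expect_named(re, c("tree1", "tree2", "n", "mast", "icong", "p", "significant"))
  lines <- readLines(md)
  expect_true(any(grepl("\\|", lines)))
  # every cell matches the "Icong; p" shape
  expect_match(lines[3], "[0-9]+\\.[0-9]{2}; ")
  out <- capture.output(print(tab))
  expect_true(any(grepl(";", out)))
})
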