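test_that("segment classification follows the visualisation and 70%-thinner rules", {
  expect_equal(classify_segment(2.0, 2.1, visualized = TRUE), "normal")
  # 75% thinner than contralateral -> variation
  expect_equal(classify_segment(0.25, 1.0, visualized = TRUE), "variation")
  expect_equal(classify_segment(0, NULL, visualized = FALSE), "variation")
  # threshold is strict: exactly 70% thinner (0.30x) is still normal
  expect_equal(classify_segment(0.30, 1.0, visualized = TRUE), "normal")
  # fused bilateral ACAs: Aco counts normal even if not visualised
  expect_equal(classify_segment(0, NULL, visualized = FALSE, fused = TRUE),
               "normal")
  expect_error(classify_segment(-1, 1, TRUE), "negative")
})

test_that("completeness flags follow the anterior/posterior partition", {
  all_normal <- cow_configuration(setNames(rep("normal", 7),
    c("Aco", "A1_L", "A1_R", "Pco_L", "Pco_R", "P1_L", "P1_R")))
  expect_equal(classify_completeness(all_normal),
               list(entire = TRUE, anterior = TRUE, posterior = TRUE))
  pco <- all_normal; pco$statuses["Pco_L"] <- "variation"
  expect_equal(classify_completeness(pco),
               list(entire = FALSE, anterior = TRUE, posterior = FALSE))
  aco <- all_normal; aco$statuses["Aco"] <- "variation"
  expect_equal(classify_completeness(aco),
               list(entire = FALSE, anterior = FALSE, posterior = TRUE))
})

test_that("completeness is consistent: entire complete implies both parts", {
  segs <- c("Aco", "A1_L", "A1_R", "Pco_L", "Pco_R", "P1_L", "P1_R")
  set.seed(10)
  for (i in 1:25) {
    st <- setNames(sample(c("normal", "variation"), 7, replace = TRUE), segs)
    fl <- classify_completeness(cow_configuration(st))
    expect_equal(fl$entire, fl$anterior && fl$posterior)
  }
})

test_that("NASCET grading respects the printed band edges and is monotone", {
  expect_equal(as.character(grade_stenosis(0)$grade), "normal")
  expect_equal(as.character(grade_stenosis(29)$grade), "mild")
  expect_equal(as.character(grade_stenosis(30)$grade), "moderate")
  expect_equal(as.character(grade_stenosis(69.9)$grade), "moderate")
  expect_equal(as.character(grade_stenosis(70)$grade), "severe")
  expect_equal(as.character(grade_stenosis(100)$grade), "severe")
  expect_error(grade_stenosis(101), "0, 100")
  grades <- vapply(seq(0, 100, by = 0.5), function(p)
    as.integer(grade_stenosis(p)$grade), integer(1))
  expect_true(all(diff(grades) >= 0))
})

test_that("counts are reconstructed from printed (n, %) rows with round-trip check", {
  expect_equal(reconstruct_counts(53, 36), 19L)
  expect_equal(reconstruct_counts(27, 59), 16L)
  expect_equal(reconstruct_counts(40, 0), 0L)
  expect_warning(reconstruct_counts(3, 50), "re-rounds")
})

test_that("chi-square is Pearson without continuity correction", {
  r <- chi_square_test(rbind(c(19, 34), c(16, 11)))
  expect_equal(r$df, 1)
  expect_equal(round(r$p_value, 3), 0.046)
  flat <- chi_square_test(rbind(c(10, 10), c(10, 10)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_equal(round(chi_square_test(rbind(c(12, 28), c(22, 18)))$p_value, 3),
               0.024)
  expect_error(chi_square_test(rbind(c(0, 0), c(5, 5))), "margin")
  expect_error(chi_square_test(matrix(1, 3, 3)), "2x2")
})

test_that("summary t-test matches expectations and is monotone in n", {
  same <- t_test_two_sample(5, 1, 10, 5, 1, 10)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  ages <- t_test_two_sample(30, 4, 53, 63, 5, 27)
  expect_lt(ages$p_value, 0.001)
  p1 <- t_test_two_sample(5, 2, 10, 6, 2, 10)$p_value
  p2 <- t_test_two_sample(5, 2, 20, 6, 2, 20)$p_value
  expect_lte(p2, p1)
  degen <- t_test_two_sample(5, 0, 10, 5, 0, 10)
  expect_equal(degen$p_value, 1)
  expect_error(t_test_two_sample(5, 0, 10, 6, 0, 10), "degenerate")
  # Welch form agrees with base R on raw data summaries
  set.seed(1)
  x <- rnorm(15, 1); y <- rnorm(12, 2)
  w <- t_test_two_sample(mean(x), sd(x), 15, mean(y), sd(y), 12, welch = TRUE)
  ref <- t.test(x, y)
  expect_equal(w$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("group comparisons reproduce the printed prevalence p-values", {
  tab <- cow_table2()
  res <- compare_groups(tab, c("Aco", "anterior_incomplete"),
                        list(c("Yn", "Sn"), c("Male", "Female")))
  get_p <- function(g1, oc)
    res$p[res$group1 == g1 & res$outcome == oc]
  expect_equal(round(get_p("Yn", "Aco"), 3), 0.046)
  expect_equal(round(get_p("Yn", "anterior_incomplete"), 3), 0.009)
  expect_equal(round(get_p("Male", "Aco"), 3), 0.024)
  expect_equal(round(get_p("Male", "anterior_incomplete"), 3), 0.044)
  post <- compare_groups(tab, c("P1", "posterior_incomplete"),
                         list(c("ESs", "Ec")))
  expect_equal(round(post$p, 3), c(0.072, 0.087))
  expect_false(any(post$significant))
  # self-comparison is always flat
  self <- compare_groups(tab, c("Aco", "P1"), list(c("Yn", "Yn")))
  expect_true(all(self$p == 1))
  expect_error(compare_groups(tab, "Aco", list(c("Yn", "Zz"))), "unknown group")
  expect_error(compare_groups(tab, "nope", list(c("Yn", "Sn"))),
               "unknown outcome")
})

test_that("stenosis measurement returns 0 for uniform tubes and 100 for occlusion", {
  p <- generate_phantom(phantom_spec(volume_shape = c(96, 96, 96),
                                     spacing_mm = 2 / 3,
                                     segment_statuses = only_segments("ICA_L"),
                                     noise_sd = 0, bias_field_amplitude = 0,
                                     seed = 4L))
  expect_lt(measure_stenosis_pct(p$mask, p$tree$ICA_L), 5)
  occl <- generate_phantom(phantom_spec(volume_shape = c(96, 96, 96),
                                        spacing_mm = 2 / 3,
                                        segment_statuses = only_segments("ICA_L"),
                                        stenoses = list(list(segment = "ICA_L",
                                                             position = 0.5,
                                                             severity_pct = 99.9)),
                                        noise_sd = 0,
                                        bias_field_amplitude = 0, seed = 4L))
  expect_equal(measure_stenosis_pct(occl$mask, occl$tree$ICA_L), 100)
  empty <- volume(array(0L, c(96, 96, 96)), 2 / 3)
  expect_equal(measure_stenosis_pct(empty, p$tree$ICA_L), 100)
  expect_error(measure_stenosis_pct(p$mask, p$tree$Aco), "absent")
})

test_that("phantom classification matches the generative statuses", {
  p <- quiet_phantom(segment_statuses = list(Aco = "absent",
                                             Pco_L = "hypoplastic",
                                             P1_R = "absent"))
  cfg <- classify_phantom(p)
  expect_equal(unname(cfg$statuses["Aco"]), "variation")
  expect_equal(unname(cfg$statuses["Pco_L"]), "variation")
  expect_equal(unname(cfg$statuses["P1_R"]), "variation")
  expect_equal(unname(cfg$statuses["A1_L"]), "normal")
  expect_equal(unname(cfg$statuses["P1_L"]), "normal")
})
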