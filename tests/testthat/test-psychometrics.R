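test_that("mssd matches hand-worked values and handles gaps", {
  expect_equal(mssd(c(1, 1, 1)), 0)
  expect_equal(mssd(c(1, 3)), 4.0)
  expect_equal(mssd(c(2, 4, 2)), 4.0)
  # missing time-points are dropped before differencing
  expect_equal(mssd(c(2, NA, 4)), 4.0)
  expect_true(is.na(mssd(c(3))))
  expect_true(is.na(mssd(c(NA, 5))))
})

test_that("within-person SD uses the sample (n-1) denominator", {
  expect_equal(within_person_sd(c(1, 1, 1)), 0)
  expect_equal(within_person_sd(c(1, 3)), sqrt(2))
  expect_equal(within_person_sd(1:7), sqrt(28 / 6))
  expect_true(is.na(within_person_sd(4)))
})

test_that("Cronbach's alpha handles perfect, noisy and degenerate scales", {
  identical_items <- cbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(cronbach_alpha(identical_items)$alpha, 1.0)

  reversed <- cbind(c(1, 2, 3), c(3, 2, 1)) # total score constant
  r <- cronbach_alpha(reversed)
  expect_true(r$undefined)
  expect_true(is.na(r$alpha))

  set.seed(31)
  noise <- matrix(stats::rnorm(2 * 10000), ncol = 2)
  expect_lt(abs(cronbach_alpha(noise)$alpha), 0.1)

  incomplete <- rbind(c(1, 2), c(2, NA), c(3, 1), c(2, 2))
  expect_identical(cronbach_alpha(incomplete)$n_rows, 3L)
})

test_that("spearman rho uses tie-aware average ranks", {
  up <- spearman_rho(1:8, (1:8)^2, exact = FALSE)
  expect_equal(up$rho, 1.0)
  down <- spearman_rho(1:8, -(1:8), exact = FALSE)
  expect_equal(down$rho, -1.0)
  tied <- spearman_rho(c(1, 2, 2, 4), c(2, 3, 3, 5))
  expect_equal(tied$rho, 1.0)
  const <- spearman_rho(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_true(const$undefined)
})

test_that("rho and its t-approximation p agree with the reference implementation", {
  set.seed(7)
  for (rep in 1:100) {
    n <- sample(8:30, 1)
    x <- sample(1:7, n, replace = TRUE) + stats::rnorm(n, 0, 0.01)
    y <- x * 0.5 + stats::rnorm(n)
    got <- spearman_rho(x, y, exact = FALSE)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  }
})

test_that("small-sample p-values come from exact permutation", {
  x <- c(3, 1, 4, 2, 5)
  y <- c(2, 1, 5, 3, 4)
  got <- spearman_rho(x, y) # n = 5 < 10 -> exact
  # oracle: exhaustive permutation distribution of rho
  rx <- rank(x); ry <- rank(y)
  perms <- emadiary:::all_permutations(5)
  rhos <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
  expect_equal(got$p, mean(abs(rhos) >= abs(got$rho) - 1e-12))
  expect_gt(got$p, 0)
  expect_lte(got$p, 1)
})

test_that("spearman rho is invariant under strictly monotone transforms", {
  set.seed(13)
  for (rep in 1:20) {
    x <- stats::rnorm(15)
    y <- stats::rnorm(15)
    base <- spearman_rho(x, y, exact = FALSE)$rho
    expect_equal(spearman_rho(exp(x), y, exact = FALSE)$rho, base)
    expect_equal(spearman_rho(x, y^3 + 2 * y, exact = FALSE)$rho, base)
  }
})

test_that("the validity table orders scales by rho and flags rare endorsement", {
  set.seed(17)
  n <- 20
  ids <- sprintf("p%02d", 1:n)
  truth <- stats::rnorm(n, 3, 1)
  summaries <- rbind(
    data.frame(
      participant_id = ids, scale_id = "anxiety",
      mean = pmin(pmax(truth + stats::rnorm(n, 0, 0.3), 1), 7)
    ),
    data.frame(
      participant_id = ids, scale_id = "hostility",
      mean = pmin(pmax(truth + stats::rnorm(n, 0, 2.5), 1), 7)
    ),
    data.frame( # floor scale: endorsed by only two participants
      participant_id = ids, scale_id = "guilty_ideas_of_reference",
      mean = c(2, 1.5, rep(1, n - 2))
    )
  )
  interviews <- data.frame(
    participant_id = ids, occasion = "followup", item_code = "PANSS_G2",
    rating = pmin(pmax(round(truth), 1), 7)
  )
  interviews <- rbind(
    interviews,
    transform(interviews, item_code = "PANSS_P7"),
    transform(interviews, item_code = "CDS_4")
  )
  mapping <- data.frame(
    scale_id = c("anxiety", "hostility", "guilty_ideas_of_reference"),
    item_code = c("PANSS_G2", "PANSS_P7", "CDS_4")
  )
  tab <- validity_table(summaries, interviews, mapping)
  analysed <- tab[!tab$excluded, ]
  expect_true(all(diff(analysed$rho) <= 0)) # descending
  expect_gt(analysed$rho[analysed$scale_id == "anxiety"],
    analysed$rho[analysed$scale_id == "hostility"])
  gir <- tab[tab$scale_id == "guilty_ideas_of_reference", ]
  expect_true(gir$excluded)
  expect_match(gir$note, "2 participant")
  expect_error(
    validity_table(summaries, interviews, mapping[1:2, ]),
    class = "emadiary_mapping_error"
  )
  # a constant interview column gives a flagged undefined row
  const_iv <- transform(interviews, rating = 3L)
  tab2 <- validity_table(
    summaries[summaries$scale_id == "anxiety", ], const_iv, mapping
  )
  expect_true(is.na(tab2$rho[1]))
  expect_match(tab2$note[1], "zero variance")
})

test_that("instability on constant data is exactly zero and delusions are restricted", {
  scores <- expand.grid(
    participant_id = c("p01", "p02"), day = 1:7, alarm_index = c(1, 3, 5),
    scale_id = c("anxiety", "delusions"), stringsAsFactors = FALSE
  )
  scores$set <- 2L
  scores$value <- 2.0
  tab <- instability_table(scores, delusion_participants = "p01")
  expect_true(all(tab$mssd_mean == 0))
  expect_true(all(tab$sd_mean == 0))
  expect_identical(tab$n_persons[tab$scale_id == "delusions"], 1L)
  expect_identical(tab$n_persons[tab$scale_id == "anxiety"], 2L)
})

test_that("reactivity is the mean of both items over completed entries", {
  log <- data.frame(
    participant_id = "p01", day = c(1, 1, 2, 2), alarm_index = c(1, 1, 2, 2),
    set = 1L, item_id = rep(c("react_thoughts", "react_mood"), 2),
    scale_id = "reactivity", response_likert = c(2L, 2L, 4L, 4L),
    answered_at_hhmm = NA_character_, status = "completed"
  )
  expect_equal(reactivity_mean(log, "p01"), 3.0)
  one <- log[1:2, ]
  one$response_likert <- c(3L, 4L)
  expect_equal(reactivity_mean(one, "p01"), 3.5)
  expect_true(is.na(reactivity_mean(log, "p99")))
})
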