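bank <- default_item_bank()

test_that("scale scores are item means with recodes applied", {
  s <- make_session(c(anx1 = 2L, anx2 = 3L, anx3 = 4L, anx4 = 3L), set = 2)
  expect_equal(score_entry_scale(s, bank$scales$anxiety), 3.0)

  g <- make_session(c(gra1 = 7L, gra2 = 2L), set = 2)
  expect_equal(score_entry_scale(g, bank$scales$grandiosity), 3.0) # mean(4, 2)

  single <- make_session(c(hal1 = 5L), set = 1)
  expect_equal(score_entry_scale(single, bank$scales$hallucinations), 5.0)
})

test_that("hidden branch items are excluded, not imputed", {
  # gui3/gui4 never displayed: mean over the two stems only
  s <- make_session(c(gui1 = 1L, gui2 = 3L), set = 1)
  expect_equal(score_entry_scale(s, bank$scales$guilt), 2.0)
  none <- make_session(c(anx1 = 2L), set = 2)
  expect_true(is.na(score_entry_scale(none, bank$scales$guilt)))
})

test_that("scoring is invariant to item order within a scale", {
  sc <- bank$scales$anxiety
  s <- make_session(c(anx1 = 2L, anx2 = 5L, anx3 = 3L, anx4 = 6L), set = 2)
  shuffled <- sc
  shuffled$items <- sc$items[c(3, 1, 4, 2)]
  expect_equal(score_entry_scale(s, sc), score_entry_scale(s, shuffled))
})

test_that("the delusions composite mixes delusion items with three scale means", {
  view <- configure_delusions(bank, "tpl_conspiracy")
  resp <- c(
    del_tpl_conspiracy_stem = 2L, del_tpl_conspiracy_preoccupation = 3L,
    del_tpl_conspiracy_distress = 2L, del_tpl_conspiracy_impact = 3L,
    gra1 = 1L, # recoded grandiosity mean 1
    som1 = 1L, som2 = 1L, # somatic mean 1
    sus1 = 2L # suspiciousness mean 2
  )
  s <- make_session(resp, set = 2)
  expect_equal(
    composite_delusions(s, view),
    mean(c(2, 3, 2, 3, 1, 1, 2))
  )
})

test_that("with no delusions configured the composite is the mean of three means", {
  view <- configure_delusions(bank, character())
  s <- make_session(c(gra1 = 5L, som1 = 4L, sus1 = 3L), set = 2)
  # grandiosity 5 recodes to 2
  expect_equal(composite_delusions(s, view), mean(c(2, 4, 3)))
  floor_s <- make_session(c(gra1 = 1L, som1 = 1L, sus1 = 1L), set = 2)
  expect_equal(composite_delusions(floor_s, view), 1.0)
})

test_that("the depression composite appends the hopelessness mean", {
  s <- make_session(c(dep1 = 3L, dep2 = 3L, hop1 = 3L, hop2 = 3L), set = 1)
  expect_equal(composite_depression(s, bank), 3.0)
  s2 <- make_session(c(dep1 = 2L, dep2 = 4L, hop1 = 1L, hop2 = 1L), set = 1)
  expect_equal(composite_depression(s2, bank), mean(c(2, 4, 1)))
  s7 <- make_session(c(dep1 = 7L, dep2 = 7L, hop1 = 7L, hop2 = 7L), set = 1)
  expect_equal(composite_depression(s7, bank), 7.0)
})

test_that("person means skip missing time-points", {
  expect_equal(person_mean(2), 2.0)
  expect_equal(person_mean(c(1, 3, 5)), 3.0)
  expect_equal(person_mean(c(2, NA, 4)), 3.0)
  expect_true(is.na(person_mean(numeric(0))))
  expect_true(is.na(person_mean(NA_real_)))
})

test_that("the compliance rule requires 14 of 42 and matches brute force everywhere", {
  rule <- compliance_rule()
  expect_identical(rule$threshold_count, 14L)
  expect_true(classify_compliance(14, rule))
  expect_false(classify_compliance(13, rule))
  expect_true(classify_compliance(42, rule))
  for (np in 1:100) {
    r <- compliance_rule(n_possible = np)
    # brute force: smallest count whose fraction reaches the threshold
    ok <- which((0:np) / np >= r$fraction_threshold - 1e-12) - 1L
    smallest <- if (length(ok) > 0) min(ok) else np + 1L
    got <- vapply(0:np, classify_compliance, NA, rule = r)
    expect_identical(got, (0:np) >= smallest)
  }
})

test_that("completion percentages round to the nearest integer", {
  expect_identical(completion_percent(36, 44), 82L)
  expect_identical(completion_percent(0, 42), 0L)
  expect_identical(completion_percent(21, 42), 50L)
})

test_that("scores and summaries stay on the 1-7 continuum", {
  view <- configure_delusions(bank, "tpl_conspiracy")
  set.seed(21)
  sessions <- lapply(1:12, function(t) {
    administer_session(view, assign_set(t), function(...) stats::runif(1),
      day = (t - 1) %/% 6 + 1, alarm_index = (t - 1) %% 6 + 1
    )
  })
  scores <- score_sessions(sessions, view)
  expect_true(all(scores$value >= 1 & scores$value <= 7))
  summ <- person_summaries(scores, rule = compliance_rule(n_possible = 12))
  expect_true(all(summ$mean >= 1 & summ$mean <= 7))
  expect_true(all(summ$n_completed <= summ$n_possible))
})
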