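test_that("packaged bank loads with the full instrument structure", {
  bank <- default_item_bank()
  expect_s3_class(bank, "ema_bank")
  expect_length(bank$scales, 14)
  expect_length(bank$delusion_templates, 6)
  expect_length(bank$reactivity_items, 2)
  sets <- vapply(bank$scales, `[[`, 0L, "set")
  expect_setequal(
    names(sets)[sets == 1],
    c(
      "guilt", "hopelessness", "depression", "social_withdrawal",
      "conceptual_disorganisation", "excitement", "hallucinations"
    )
  )
  expect_setequal(
    names(sets)[sets == 2],
    c(
      "anxiety", "grandiosity", "hostility", "somatic_concern",
      "guilty_ideas_of_reference", "suspiciousness", "delusions"
    )
  )
  for (tp in bank$delusion_templates) expect_length(tp$sub_items, 3)
})

test_that("invalid documents raise distinct validation errors naming the offender", {
  doc <- read_bank_doc()
  doc13 <- doc
  doc13$scales <- doc13$scales[-1] # drop guilt
  expect_error(
    load_item_bank(write_bank_doc(doc13)),
    "guilt",
    class = "emadiary_scale_count_error"
  )

  dangling <- doc
  dangling$scales[[1]]$items[[3]]$display_condition$source <- "nonexistent"
  expect_error(
    load_item_bank(write_bank_doc(dangling)),
    "nonexistent",
    class = "emadiary_branch_error"
  )

  five_tpl <- doc
  five_tpl$delusion_templates <- five_tpl$delusion_templates[1:5]
  expect_error(
    load_item_bank(write_bank_doc(five_tpl)),
    "5",
    class = "emadiary_template_error"
  )

  # turning three set-1 stems into branches drops the enumerated minimum to 12
  low <- doc
  for (k in 1:3) {
    low$scales[[k]]$items[[2]]$role <- "branch"
    low$scales[[k]]$items[[2]]$display_condition <-
      list(source = low$scales[[k]]$items[[1]]$item_id, op = ">=", threshold = 2)
  }
  expect_error(
    load_item_bank(write_bank_doc(low)),
    "12",
    class = "emadiary_count_error"
  )
})

test_that("question-count enumeration matches brute force on random components", {
  set.seed(42)
  for (rep in 1:150) {
    items <- random_component(sample(2:4, 1))
    got <- emadiary:::enumerate_component(items)
    want <- oracle_component_counts(items)
    expect_identical(as.integer(got), as.integer(want))
  }
})

test_that("a branch-free set enumerates to a fixed count", {
  doc <- read_bank_doc()
  for (k in seq_along(doc$scales)) {
    doc$scales[[k]]$items <- Filter(
      function(it) is.null(it$display_condition), doc$scales[[k]]$items
    )
  }
  bank <- emadiary:::build_item_bank(doc) # bounds invariant no longer holds
  cnt <- enumerate_question_counts(bank, 1)
  expect_identical(cnt[["min"]], cnt[["max"]])
  expect_identical(cnt[["min"]], 13L + 2L) # 13 set-1 stems + 2 reactivity
})

test_that("analogue conversion uses seven equal-width bins", {
  expect_identical(analogue_to_likert(0), 1L)
  expect_identical(analogue_to_likert(1), 7L)
  expect_identical(analogue_to_likert(0.5), 4L)
  grid <- seq(0, 1, by = 0.001)
  lik <- analogue_to_likert(grid)
  expect_true(all(diff(lik) >= 0)) # monotone
  expect_setequal(unique(lik), 1:7) # surjective
  # bin k covers [(k-1)/7, k/7)
  expect_identical(analogue_to_likert(1 / 7 - 1e-9), 1L)
  expect_identical(analogue_to_likert(1 / 7), 2L)
  expect_error(analogue_to_likert(1.01), class = "emadiary_range_error")
  expect_error(analogue_to_likert(-0.01), class = "emadiary_range_error")
})

test_that("grandiosity recode collapses the lower half as printed", {
  expect_identical(recode_grandiosity1(1:7), c(1L, 1L, 1L, 1L, 2L, 3L, 4L))
  expect_error(recode_grandiosity1(0), class = "emadiary_range_error")
  expect_error(recode_grandiosity1(8), class = "emadiary_range_error")
})

test_that("branch conditions evaluate against earlier responses", {
  cond <- list(source = "a", op = ">=", threshold = 2)
  expect_true(evaluate_branch(cond, c(a = 3L)))
  expect_false(evaluate_branch(cond, c(a = 1L)))
  expect_false(evaluate_branch(cond, c(b = 7L))) # unanswered source hides
  expect_true(evaluate_branch(list(source = "a", op = "=", threshold = 4), c(a = 4L)))
  expect_false(evaluate_branch(list(source = "a", op = ">", threshold = 4), c(a = 4L)))
})

test_that("delusion personalisation touches only the delusions scale", {
  bank <- default_item_bank()
  v2 <- configure_delusions(bank, c("tpl_conspiracy", "tpl_mind_reading"))
  expect_length(v2$scales$delusions$items, 8) # 2 x (statement + 3 sub-items)
  v0 <- configure_delusions(bank, character())
  expect_length(v0$scales$delusions$items, 0)
  for (sid in setdiff(names(bank$scales), "delusions")) {
    expect_identical(v2$scales[[sid]], bank$scales[[sid]])
  }
  expect_error(
    configure_delusions(bank, names(bank$delusion_templates)[1:3]),
    "maximum of 2",
    class = "emadiary_delusion_limit_error"
  )
  expect_error(
    configure_delusions(bank, "tpl_unknown"),
    class = "emadiary_delusion_id_error"
  )
})
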