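muscles4 <- c("Q_left", "Q_right", "TS_left", "TS_right")

test_that("a grid with its first reflex at 15 mA yields 13.5 mA", {
  g <- make_grid(4, seq(5, 30, 5), function(p, cur, m) {
    if (cur >= 15 && m %in% c("Q_left", "Q_right")) 1L else 0L
  })
  sel <- select_position_current(g)
  expect_equal(sel$position, 4)
  frc <- first_reflex_current(g, sel$position)
  expect_equal(frc, 15)
  expect_equal(therapy_current(frc), 0.9 * 15)
  expect_equal(therapy_current(frc), 13.5)
})

test_that("rule 1 eliminates positions without a two-muscle reflex", {
  # position B has two class-1 labels at 20 mA; A never more than one
  g <- make_grid(c(0, 4), c(10, 15, 20), function(p, cur, m) {
    if (p == 4 && cur == 20 && m %in% c("Q_left", "Q_right")) 1L
    else if (p == 0 && cur == 20 && m == "Q_left") 1L
    else 0L
  })
  expect_equal(select_position_current(g)$position, 4)
})

test_that("an all-quiet grid selects nothing and maps to 0 mA", {
  g <- make_grid(c(0, 4), seq(5, 25, 5), function(p, cur, m) 0L)
  expect_null(select_position_current(g))
  params <- derive_therapy_params(
    tibble::tibble(subject_id = "X", group = "healthy", measurement = "d1",
                   position = g$position, current = g$current,
                   muscle = g$muscle, label_3 = g$label))
  expect_equal(params$therapy_current, 0)
  expect_true(is.na(params$position))
})

test_that("total reflex count breaks ties left by rules 1-4", {
  # both positions: two class-1 at 15 mA, same onset; position 0 has an
  # extra reflex label at a higher current
  g <- make_grid(c(0, 4), c(10, 15, 20), function(p, cur, m) {
    if (cur == 15 && m %in% c("Q_left", "Q_right")) 1L
    else if (p == 0 && cur == 20 && m == "TS_left") 1L
    else 0L
  })
  expect_equal(select_position_current(g)$position, 0)
  # and with identical grids the residual tie goes to the caudal position
  g2 <- make_grid(c(-4, 4), c(10, 15), function(p, cur, m) {
    if (cur == 15 && m %in% c("Q_left", "Q_right")) 1L else 0L
  })
  expect_equal(select_position_current(g2)$position, -4)
  # determinism: same grid, same answer
  expect_identical(select_position_current(g2),
                   select_position_current(g2))
})

test_that("first reflex current is the grid minimum with a class-1 label", {
  g <- make_grid(0, c(10, 15, 20), function(p, cur, m) {
    if (cur >= 10 && m == "Q_left") 1L else 0L
  })
  expect_equal(first_reflex_current(g, 0), 10)
  g$label[g$current == 10] <- 0L
  expect_equal(first_reflex_current(g, 0), 15)
  g$label <- 0L
  expect_true(is.na(first_reflex_current(g, 0)))
})

test_that("therapy current is exactly 90% of the first reflex current", {
  expect_equal(therapy_current(15), 13.5)
  expect_equal(therapy_current(20), 18)
  expect_equal(therapy_current(0), 0)
  expect_error(therapy_current(-5))
})

test_that("agreement rows follow the EMG-minus-predicted convention", {
  base <- tibble::tibble(subject_id = "X", group = "healthy",
                         measurement = "d1", position = 4,
                         first_reflex = 15, therapy_current = 13.5,
                         n_positions = 2L)
  # identical parameters agree everywhere
  cmp <- compare_therapy_params(base, base)
  expect_equal(cmp$current_diff, 0)
  expect_true(cmp$exact_current && cmp$within_margin && cmp$position_match)
  # predicted 5 mA higher: diff negative, inside the margin
  pred <- base; pred$therapy_current <- 18.5
  cmp <- compare_therapy_params(base, pred)
  expect_equal(cmp$current_diff, -5)
  expect_false(cmp$exact_current)
  expect_true(cmp$within_margin)
  # 10 mA off: outside
  pred$therapy_current <- 23.5
  expect_false(compare_therapy_params(base, pred)$within_margin)
  # single-position measurements carry no position verdict
  b1 <- base; b1$n_positions <- 1L
  expect_true(is.na(compare_therapy_params(b1, b1)$position_match))
  s <- agreement_summary(compare_therapy_params(base, pred))
  expect_equal(s$prop_exact_current, 0)
  expect_equal(s$prop_position, 1)
})

test_that("EMG-derived parameters recover the generator's best position", {
  tabs <- small_tables()
  params <- derive_therapy_params(tabs$features, "label_3")
  truth <- tabs$truth %>%
    dplyr::distinct(subject_id, measurement, best_position)
  joined <- dplyr::inner_join(params, truth,
                              by = c("subject_id", "measurement"))
  multi <- joined[joined$n_positions > 1, ]
  expect_true(all(multi$position == multi$best_position))
  # therapy currents sit on the 90% sub-motor rule wherever found
  found <- params[params$therapy_current > 0, ]
  expect_equal(found$therapy_current, 0.9 * found$first_reflex)
})
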