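test_that("wide CSV round-trips bit-identically and long format agrees", {
  pnl <- toy_panel(n = 4, p = 4)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_panel(pnl, tmp)
  back <- read_panel(tmp, pnl$codebook)
  expect_identical(back$values, pnl$values)
  expect_identical(back$group, pnl$group)

  # second write of the re-read panel is byte-identical
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_panel(back, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))

  # same data through the long dialect gives the same panel
  cb_long <- toy_codebook(4, format = "long")
  pnl_long <- binary_panel(pnl$values, group = pnl$group, codebook = cb_long)
  tmp3 <- withr::local_tempfile(fileext = ".csv")
  write_panel(pnl_long, tmp3)
  back_long <- read_panel(tmp3, cb_long)
  expect_equal(unname(back_long$values), unname(pnl$values))
})

test_that("invalid cells and unknown columns are rejected with location", {
  pnl <- toy_panel(n = 3, p = 3)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_panel(pnl, tmp)
  lines <- readLines(tmp)
  lines[2] <- sub("^([^,]*,[^,]*,)[01]", "\\12", lines[2])
  writeLines(lines, tmp)
  expect_error(read_panel(tmp, pnl$codebook), "invalid value '2'.*line 2")

  write_panel(pnl, tmp)
  lines <- readLines(tmp)
  lines[1] <- paste0(lines[1], ",Mystery")
  lines[-1] <- paste0(lines[-1], ",0")
  writeLines(lines, tmp)
  expect_error(read_panel(tmp, pnl$codebook), "unknown item column")
})

test_that("inclusion filter excludes by first applicable flowchart reason", {
  pnl <- toy_panel(n = 6, p = 4)
  pnl$values[2, 3, 2] <- NA                # one item missing at wave 2
  pnl$values[3, , 2] <- NA                 # entire wave 2 absent
  pnl$group[4] <- NA                       # diabetes question unanswered
  pnl$values[4, 1, 1] <- NA                # ...and also a missing item
  res <- apply_inclusion_filter(pnl)
  expect_equal(res$exclusion_log$excluded$missing_item, 1)
  expect_equal(res$exclusion_log$excluded$single_wave, 1)
  expect_equal(res$exclusion_log$excluded$missing_group, 1)
  expect_equal(res$exclusion_log$retained, 3)
  expect_false(anyNA(res$panel$values))

  # idempotent on the filtered result; identity on complete panels
  res2 <- apply_inclusion_filter(res$panel)
  expect_identical(res2$panel$values, res$panel$values)
  expect_equal(res2$exclusion_log$excluded$missing_item, 0)

  clean <- toy_panel(n = 5, p = 4)
  resc <- apply_inclusion_filter(clean)
  expect_identical(resc$panel$values, clean$values)

  allna <- toy_panel(n = 2, p = 4)
  allna$group[] <- NA
  expect_error(apply_inclusion_filter(allna), "no subjects remain")
})

test_that("group split partitions subjects and conserves counts", {
  pnl <- toy_panel(n = 8, p = 4,
                   group = c(rep("diabetes", 3), rep("no_diabetes", 5)))
  sp <- split_by_group(pnl)
  expect_equal(n_subjects(sp$diabetes), 3)
  expect_equal(n_subjects(sp$no_diabetes), 5)
  expect_equal(n_subjects(sp$diabetes) + n_subjects(sp$no_diabetes),
               n_subjects(pnl))
  expect_setequal(c(sp$diabetes$subject_ids, sp$no_diabetes$subject_ids),
                  pnl$subject_ids)

  one <- toy_panel(n = 4, p = 4, group = rep("diabetes", 4))
  expect_warning(sp1 <- split_by_group(one), "one group is empty")
  expect_equal(n_subjects(sp1$no_diabetes), 0)
})

test_that("behaviour recoding follows the survey coding rules", {
  # current smoker coded 1; never-smoker via either question coded 0
  expect_equal(recode_behaviours(list(smoke_now = "yes"))[["S"]], 1)
  expect_equal(recode_behaviours(list(smoke_now = "no"))[["S"]], 0)
  expect_equal(recode_behaviours(list(smoke_ever = "no"))[["S"]], 0)
  # life-long non-drinkers score 0 on heavy episodic drinking
  expect_equal(
    recode_behaviours(list(drinks_alcohol = "never",
                           drinks_6plus = "never"))[["D"]], 0)
  expect_equal(
    recode_behaviours(list(drinks_6plus = "at_least_once"))[["D"]], 1)
  # daily fruit/veg eaters coded 0
  expect_equal(recode_behaviours(list(fruitveg = "daily"))[["F"]], 0)
  expect_equal(recode_behaviours(list(fruitveg = "less_than_daily"))[["F"]], 1)
  # inactivity means never vigorous nor moderate activity
  expect_equal(
    recode_behaviours(list(activity = "never_vigorous_nor_moderate"))[["P"]], 1)
  expect_equal(recode_behaviours(list(activity = "other"))[["P"]], 0)
  # unanswered questions propagate as missing, invalid answers error
  expect_true(is.na(recode_behaviours(list())[["S"]]))
  expect_error(recode_behaviours(list(smoke_now = "sometimes")),
               "invalid answer")
})
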