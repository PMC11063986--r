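test_that("outcome labeling honors the class boundaries", {
  expect_equal(as.character(label_outcome(100, 0)), "CR")
  expect_equal(as.character(label_outcome(100, 70)), "PR")    # -30%: "at least"
  expect_equal(as.character(label_outcome(100, 71)), "SNG")
  expect_equal(as.character(label_outcome(100, 120)), "SNG")  # +20%: "over"
  expect_equal(as.character(label_outcome(100, 121)), "PNG")
  expect_equal(as.character(label_outcome(100, 100)), "SNG")
  expect_error(label_outcome(0, 10), "initial_living")
  expect_error(label_outcome(100, -1), "final_living")
})

test_that("the four classes partition all population changes", {
  ratios <- seq(0, 2, by = 0.001)
  labs <- label_outcome(rep(1000, length(ratios)), round(1000 * ratios))
  expect_false(anyNA(labs))
  expect_setequal(as.character(unique(labs)), c("CR", "PR", "SNG", "PNG"))
  # single-valued: vectorized call agrees with elementwise calls
  idx <- seq(1, length(ratios), by = 97)
  single <- vapply(idx, function(i)
    as.character(label_outcome(1000, round(1000 * ratios[i]))), "")
  expect_equal(as.character(labs[idx]), single)
})

test_that("named protocols expand to the right event lists", {
  s1 <- make_schedule("T1", 0.3, 5)
  expect_equal(nrow(s1$events), 2L)
  expect_true(all(s1$events$time == 0))

  s2 <- make_schedule("T2", 0.3, 5)
  expect_equal(s2$events$time[s2$events$drug == "doxorubicin"], 17)
  expect_equal(s2$events$time[s2$events$drug == "bapn"], 0)

  s5 <- make_schedule("T5", 0.3, 5)
  expect_equal(nrow(s5$events), 4L)
  expect_equal(sort(unique(s5$events$time)), c(0, 17))
  expect_setequal(unique(s5$events$drug), c("doxorubicin", "bapn"))

  s3 <- make_schedule("T3", 0.3, 5)
  expect_equal(sum(s3$events$drug == "bapn"), 2L)
  expect_equal(sum(s3$events$drug == "doxorubicin"), 1L)

  z <- make_schedule("T2", 0, 5)
  expect_equal(z$events$dose[z$events$drug == "doxorubicin"], 0)
  expect_equal(z$events[z$events$dose > 0, ]$drug, "bapn")
  expect_equal(z$events[z$events$dose > 0, ]$time, 0)

  expect_error(make_schedule("T9", 0.3, 5), "unknown protocol")
  # events always sorted by time
  for (pr in c("T1", "T2", "T3", "T4", "T5"))
    expect_false(is.unsorted(make_schedule(pr, 0.1, 2)$events$time))
  expect_error(treatment_schedule(
    data.frame(drug = "aspirin", dose = 1, time = 0)), "drug")
})

test_that("prevalence tables count correctly and rows sum to 100", {
  labels <- data.frame(protocol = "T1", stratum = 0,
                       class = c("PR", "SNG", "SNG"))
  tab <- prevalence_table(labels)
  expect_equal(tab$PR, 100 / 3, tolerance = 1e-9)
  expect_equal(tab$SNG, 200 / 3, tolerance = 1e-9)
  expect_equal(tab$PNG, 0)
  expect_equal(tab$CR, 0)

  all_cr <- data.frame(protocol = "T1", stratum = 0, class = rep("CR", 5))
  expect_equal(prevalence_table(all_cr)$CR, 100)

  set.seed(31)
  big <- data.frame(protocol = sample(c("T1", "T2"), 1000, TRUE),
                    stratum = sample(c(0, 0.5), 1000, TRUE),
                    class = sample(outcome_classes(), 1000, TRUE))
  tab <- prevalence_table(big)
  sums <- rowSums(tab[outcome_classes()])
  expect_true(all(abs(sums - 100) < 0.01))
  # brute-force tally oracle
  for (r in seq_len(nrow(tab))) {
    sub <- big[big$protocol == tab$protocol[r] & big$stratum == tab$stratum[r], ]
    for (cl in outcome_classes()) {
      cnt <- 0
      for (x in sub$class) if (x == cl) cnt <- cnt + 1
      expect_equal(tab[r, cl], 100 * cnt / nrow(sub), tolerance = 1e-12)
    }
  }
})

test_that("changes vs the reference protocol use reference class counts", {
  mk <- function(proto, classes)
    data.frame(protocol = proto, stratum = 0, class = classes)
  labels <- rbind(mk("T1", rep(c("PR", "SNG"), c(40, 60))),
                  mk("T2", rep(c("PR", "SNG"), c(66, 34))))
  ch <- percent_change_vs_reference(labels, "T1")
  expect_equal(ch$change_pct[ch$protocol == "T1"], rep(0, 4))
  expect_equal(ch$change_pct[ch$protocol == "T2" & ch$class == "PR"], 65)
  # degenerate denominator: zero reference with positive count is flagged
  labels2 <- rbind(mk("T1", rep("PR", 10)), mk("T2", rep(c("PR", "CR"), c(8, 2))))
  ch2 <- percent_change_vs_reference(labels2, "T1")
  cr <- ch2[ch2$protocol == "T2" & ch2$class == "CR", ]
  expect_true(cr$undefined)
  expect_true(is.na(cr$change_pct))
  sng <- ch2[ch2$protocol == "T2" & ch2$class == "SNG", ]
  expect_false(sng$undefined)   # 0 -> 0 is an unambiguous zero change
  expect_equal(sng$change_pct, 0)
  expect_error(percent_change_vs_reference(labels, "T4"), "not present")
})
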