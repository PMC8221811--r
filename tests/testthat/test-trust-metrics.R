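test_that("fractional-change vectors match hand-computed arithmetic", {
  ## investor 10 -> 15 of endowment 20; trustee returns 15 of 30 then 20 of 45
  ex <- trust_exchange(investor = c(10, 15), trustee = c(15, 20),
                       endowment = 20)
  rv <- round_vectors(ex)
  expect_equal(rv$dI, 0.25)
  expect_equal(rv$dT, 20 / 45 - 15 / 30, tolerance = 1e-12)
  expect_equal(round(rv$dT, 4), -0.0556)
  expect_equal(rv$angle_deg, atan2(-1 / 18, 0.25) * 180 / pi)
  expect_equal(rv$class, "repairing")
})

test_that("quadrant classes follow the angle convention, closed above", {
  cases <- list(
    list(v = c(-0.2, -0.2), class = "retaliating"),   # -135 degrees
    list(v = c(0.2, -0.2), class = "repairing"),
    list(v = c(0.2, 0.2), class = "honoring"),
    list(v = c(-0.2, 0.2), class = "disrupting"),
    list(v = c(0.2, 0), class = "repairing"),         # 0 on the closed edge
    list(v = c(0, 0.2), class = "honoring"),          # 90 closed
    list(v = c(-0.2, 0), class = "disrupting"),       # 180
    list(v = c(0, -0.2), class = "retaliating"))      # -90 closed
  for (cs in cases)
    expect_equal(dacuity:::classify_angle(atan2(cs$v[2], cs$v[1]) * 180 / pi),
                 cs$class, info = paste(cs$v, collapse = ","))
})

test_that("zero vectors are unclassified and excluded from the resultant", {
  ex <- trust_exchange(investor = c(10, 10, 14), trustee = c(15, 15, 30),
                       endowment = 20)
  rv <- round_vectors(ex)
  expect_true(is.na(rv$class[1])); expect_true(is.na(rv$angle_deg[1]))
  sc <- exchange_scores(ex)
  expect_equal(sc$initial_trust, 0.5)
  ## all-zero exchange has no orientation
  flat <- trust_exchange(investor = c(10, 10), trustee = c(15, 15),
                         endowment = 20)
  expect_error(exchange_scores(flat), "orientation undefined")
})

test_that("invalid exchanges are rejected", {
  expect_error(trust_exchange(c(10), c(5)), "at least 2 rounds")
  expect_error(trust_exchange(c(10, 25), c(5, 5), endowment = 20),
               "endowment")
  expect_error(trust_exchange(c(10, 5), c(40, 5), endowment = 20),
               "investment")
  ex0 <- trust_exchange(c(10, 0), c(15, 0), endowment = 20)
  expect_silent(round_vectors(ex0))          # zero investment, zero return: ok
  ex_bad <- trust_exchange(c(10, 0), c(15, 0), endowment = 20)
  ex_bad$trustee[2] <- 5                     # return without investment
  expect_error(round_vectors(ex_bad), "invalid exchange")
})

test_that("whole-exchange scores: orientation, responsiveness, cooperativeness", {
  ## constant (0.1, 0.1) steps: orientation 45, responsiveness 0.1*sqrt(2)
  inv <- seq(2, 20, by = 2)
  tf <- seq(0.1, 1.0, by = 0.1)
  ex <- trust_exchange(inv, tf * 3 * inv, endowment = 20)
  sc <- exchange_scores(ex)
  expect_equal(sc$orientation_deg, 45, tolerance = 1e-9)
  expect_equal(sc$responsiveness, 0.1 * sqrt(2), tolerance = 1e-9)
  expect_equal(exchange_scores(trust_exchange(c(12, 14), c(9, 9),
                                              endowment = 20))$initial_trust,
               0.6)
})

test_that("cooperativeness endpoints sit exactly at the two cluster poles", {
  ## orientation 0 (coaxing pole) -> 1; orientation -135 -> 0
  ex0 <- trust_exchange(c(10, 14), c(15, 21), endowment = 20)  # dT = 0
  expect_equal(round_vectors(ex0)$dT, 0)
  expect_equal(exchange_scores(ex0)$cooperativeness, 1)
  exm <- trust_exchange(c(14, 10), c(25.2, 12), endowment = 20)
  rv <- round_vectors(exm)
  expect_equal(rv$angle_deg, -135)
  expect_equal(exchange_scores(exm)$cooperativeness, 0)
})

test_that("rotation and permutation invariances of exchange scores", {
  set.seed(8)
  exs <- generate_trust_exchanges(list(type = "random"), n_exchanges = 20,
                                  seed = 14)
  for (ex in exs[1:10]) {
    rv <- round_vectors(ex)
    keep <- !(rv$dI == 0 & rv$dT == 0)
    if (!any(keep)) next
    sc <- exchange_scores(ex)
    ## negating both series rotates the resultant by 180 degrees
    res <- c(sum(rv$dI[keep]), sum(rv$dT[keep]))
    ang_neg <- atan2(-res[2], -res[1]) * 180 / pi
    delta <- (ang_neg - sc$orientation_deg) %% 360
    expect_equal(min(delta, 360 - delta), 180, tolerance = 1e-9)
    ## responsiveness is order-invariant (vector sum is commutative)
    perm <- sample(which(keep))
    expect_equal(sqrt(sum(colSums(rv[perm, c("dI", "dT")])^2)) /
                   (ex$n_rounds - 1), sc$responsiveness, tolerance = 1e-12)
  }
  ## a large random exchange set covers all four classes
  cls <- unlist(lapply(exs, function(e) round_vectors(e)$class))
  expect_setequal(stats::na.omit(unique(cls)),
                  c("retaliating", "repairing", "honoring", "disrupting"))
})

test_that("exchange records round-trip through TSV", {
  exs <- generate_trust_exchanges(list(type = "coaxing"), n_exchanges = 3,
                                  seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  d <- do.call(rbind, lapply(seq_along(exs), function(i)
    data.frame(exchange = i, round = seq_len(exs[[i]]$n_rounds),
               investor = exs[[i]]$investor, trustee = exs[[i]]$trustee,
               endowment = exs[[i]]$endowment)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_trust_exchanges(path)
  expect_length(back, 3)
  expect_equal(trust_score_table(back)[, -1], trust_score_table(exs)[, -1],
               tolerance = 1e-9, ignore_attr = TRUE)
})
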