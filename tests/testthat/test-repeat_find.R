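test_that("planted direct and inverted repeats are found exactly", {
  set.seed(41)
  base <- rand_seq(3000)
  unit <- rand_seq(600)
  s_dir <- paste0(substr(base, 1, 800), "A", unit, "A",
                  substr(base, 801, 2000), "C", unit, "C",
                  substring(base, 2001))
  rp <- find_repeats(circular_genome(s_dir, id = "d"), 500)
  expect_equal(nrow(rp), 1L)
  expect_equal(rp$length, 600L)
  expect_equal(rp$orientation, "direct")
  expect_equal(rp$pos_a, 801L)
  expect_equal(rp$pos_b, 2603L)
  expect_equal(rp$identity, 100)

  s_inv <- paste0(substr(base, 1, 800), "A", unit, "A",
                  substr(base, 801, 2000), "C", reverse_complement(unit), "C",
                  substring(base, 2001))
  rp2 <- find_repeats(circular_genome(s_inv, id = "i"), 500)
  expect_equal(nrow(rp2), 1L)
  expect_equal(rp2$orientation, "inverted")
  expect_equal(rp2$length, 600L)
})

test_that("reported repeat copies re-verify by direct sequence comparison", {
  set.seed(52)
  base <- rand_seq(4000)
  u1 <- rand_seq(450); u2 <- rand_seq(300)
  s <- paste0(substr(base, 1, 500), u1, substr(base, 501, 1500),
              reverse_complement(u2), substr(base, 1501, 2500), u1,
              substr(base, 2501, 3500), u2, substring(base, 3501))
  g <- circular_genome(s, id = "g")
  rp <- find_repeats(g, 200)
  expect_gte(nrow(rp), 2L)
  for (i in seq_len(nrow(rp))) {
    a <- substr(s, rp$pos_a[i] + 1, rp$pos_a[i] + rp$length[i])
    b <- substr(s, rp$pos_b[i] + 1, rp$pos_b[i] + rp$length[i])
    if (rp$orientation[i] == "inverted") b <- reverse_complement(b)
    expect_identical(a, b)
  }
})

test_that("the seed-and-extend finder agrees with the quadratic scan", {
  set.seed(63)
  for (trial in 1:3) {
    base <- rand_seq(2500)
    u1 <- rand_seq(sample(150:400, 1))
    u2 <- rand_seq(sample(150:400, 1))
    s <- paste0(substr(base, 1, 400), u1, substr(base, 401, 1100),
                reverse_complement(u1), substr(base, 1101, 1700), u2,
                substr(base, 1701, 2100), u2, substring(base, 2101))
    got <- find_repeats(circular_genome(s, id = "g"), 100)
    want <- brute_repeats(s, 100)
    key <- function(df) sort(paste(df$length, df$pos_a, df$pos_b, df$orientation))
    expect_identical(key(got), key(want))
  }
})

test_that("repeat-free sequences yield an empty inventory", {
  set.seed(74)
  repeat_free <- NULL
  for (i in 1:20) {
    s <- rand_seq(3000)
    if (nrow(brute_repeats(s, 100)) == 0L) { repeat_free <- s; break }
  }
  expect_false(is.null(repeat_free))
  expect_equal(nrow(find_repeats(circular_genome(repeat_free, id = "g"), 100)), 0L)
})

test_that("raising the length floor never adds repeat pairs", {
  set.seed(85)
  base <- rand_seq(3000)
  u <- rand_seq(700)
  s <- paste0(substr(base, 1, 1000), u, substr(base, 1001, 2000), u,
              substring(base, 2001))
  lo <- find_repeats(circular_genome(s, id = "g"), 500)
  hi <- find_repeats(circular_genome(s, id = "g"), 800)
  expect_true(all(paste(hi$pos_a, hi$pos_b) %in% paste(lo$pos_a, lo$pos_b)))
  expect_lte(nrow(hi), nrow(lo))
})

test_that("subgenomic circle sizes come from the repeat spacing and sum to L", {
  set.seed(96)
  g100 <- circular_genome(rand_seq(100), id = "g")
  p1 <- predict_subgenomes(g100, list(pos_a = 10, pos_b = 60, orientation = "direct"))
  expect_equal(sort(p1$circle_sizes), c(50, 50))
  p2 <- predict_subgenomes(g100, list(pos_a = 10, pos_b = 30, orientation = "direct"))
  expect_equal(sort(p2$circle_sizes), c(20, 80))
  for (i in 1:10) {
    L <- sample(1000:50000, 1)
    a <- sample(0:(L - 2), 1); b <- sample((a + 1):(L - 1), 1)
    g <- list(circular = TRUE, length = L)
    class(g) <- "circular_genome"
    p <- predict_subgenomes(g, list(pos_a = a, pos_b = b, orientation = "direct"))
    expect_equal(sum(p$circle_sizes), L)
  }
  expect_error(predict_subgenomes(g100, list(pos_a = 1, pos_b = 50,
                                             orientation = "inverted")),
               "inverted")
})
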