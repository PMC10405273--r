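test_that("pair enumeration matches brute-force counting", {
  part <- list(s1 = 1:2, s2 = 3:4, s3 = 5:7)
  pr <- build_pair_index(part)
  # brute force: all p > q pairs excluding inactive-inactive and virt-virt
  cnt <- 0
  for (p in 2:7) for (q in 1:(p - 1)) {
    ii <- p %in% part$s1 && q %in% part$s1
    vv <- p %in% part$s3 && q %in% part$s3
    if (!ii && !vv) cnt <- cnt + 1
  }
  expect_equal(pr$n, cnt)
  expect_equal(pr$n, 17)
  expect_equal(unname(diff(pr$group_offsets)), c(4, 6, 1, 6))
})

test_that("degenerate pairs carry no valid metric and are dropped", {
  part <- list(s1 = integer(0), s2 = 1:2, s3 = 3:4)
  pr <- build_pair_index(part, occupations = c(0.5, 0.5, 0, 0))
  expect_equal(pr$n_dropped, 1)          # the (2,1) active pair
  expect_false(any(pr$pairs$group == 3))
})

test_that("empty occupied or secondary spaces are rejected", {
  expect_error(build_pair_index(list(s1 = integer(0), s2 = integer(0), s3 = 1:3)),
               "occupied")
  expect_error(build_pair_index(list(s1 = 1:3, s2 = integer(0), s3 = integer(0))),
               "secondary")
  pr1 <- build_pair_index(list(s1 = 1, s2 = integer(0), s3 = 2))
  expect_equal(pr1$n, 1)
  expect_equal(pr1$pairs$p, 2)
})

test_that("block layout covers every pair exactly once", {
  sys <- fixture_system("h2o_h2o")
  pr <- sys$pairs$A
  all_idx <- sort(unlist(pr$blocks))
  expect_equal(all_idx, seq_len(pr$n))
  # largest block is the active-active block or an active-sized sub-block
  M <- length(sys$states$A$partition$s2)
  expect_lte(max(lengths(pr$blocks)), max(M * (M - 1) / 2, M))
})
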