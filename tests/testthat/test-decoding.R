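neutral_cfg <- function(...) {
  args <- utils::modifyList(
    list(do_sample = TRUE, num_beams = 1, temperature = 1, top_p = 1,
         top_k = 0, repetition_penalty = 1, constrain_alphabet = FALSE),
    list(...))
  do.call(decode_config, args)
}

test_that("the all-neutral configuration reduces to a plain softmax", {
  logits <- c(1.5, -0.3, 0.2, 2.2)
  p <- process_logits(logits, integer(0), neutral_cfg())
  expect_equal(p, exp(logits) / sum(exp(logits)))
  expect_equal(sum(p), 1)
})

test_that("top-k truncation keeps the k largest logits (closed form)", {
  p <- process_logits(c(2, 1, 0), integer(0),
                      neutral_cfg(top_k = 2))
  expect_equal(p, c(exp(2), exp(1), 0) / (exp(2) + exp(1)))
  expect_equal(p[3], 0)
})

test_that("nucleus truncation keeps the minimal prefix reaching top_p", {
  logits <- log(c(0.5, 0.3, 0.2))
  p <- process_logits(logits, integer(0), neutral_cfg(top_p = 0.8))
  expect_equal(p, c(0.625, 0.375, 0))
  # boundary token included: top_p marginally above the first mass
  p2 <- process_logits(logits, integer(0), neutral_cfg(top_p = 0.51))
  expect_equal(p2, c(0.625, 0.375, 0))
  p3 <- process_logits(logits, integer(0), neutral_cfg(top_p = 0.5))
  expect_equal(p3, c(1, 0, 0))
})

test_that("repetition penalty divides positive and multiplies negative logits", {
  logits <- c(2, -1, 0.5)
  cfg <- neutral_cfg(repetition_penalty = 1.2)
  p <- process_logits(logits, c(1L, 2L), cfg)
  z <- c(2 / 1.2, -1 * 1.2, 0.5)
  expect_equal(p, exp(z) / sum(exp(z)))
})

test_that("raising the repetition penalty never increases a repeated token's probability", {
  withr::with_seed(31, {
    for (i in 1:50) {
      logits <- rnorm(6, sd = 2)
      rep_tok <- sample(6, 1)
      pens <- c(1, 1.1, 1.3, 1.6, 2)
      probs <- vapply(pens, function(rp)
        process_logits(logits, rep_tok,
                       neutral_cfg(repetition_penalty = rp))[rep_tok],
        numeric(1))
      expect_true(all(diff(probs) <= 1e-12))
    }
  })
})

test_that("the alphabet constraint masks everything outside the target set", {
  logits <- c(5, 4, 3, 2)
  p <- process_logits(logits, integer(0), neutral_cfg(), allowed = c(2L, 4L))
  expect_equal(p[c(1, 3)], c(0, 0))
  expect_equal(sum(p), 1)
})

test_that("masking away every token is an error", {
  expect_error(process_logits(c(1, 2), integer(0),
                              neutral_cfg(top_k = 1), allowed = 1L),
               "masked")
  expect_error(process_logits(c(1, Inf), integer(0), neutral_cfg()),
               "finite")
})

test_that("top_k = 1 concentrates all mass on the argmax (greedy equivalence)", {
  withr::with_seed(7, {
    for (i in 1:30) {
      logits <- rnorm(8)
      p <- process_logits(logits, integer(0), neutral_cfg(top_k = 1))
      expect_equal(p[which.max(logits)], 1)
      expect_equal(sum(p > 0), 1)
    }
  })
})

test_that("empirical sampling frequencies match the analytic distribution", {
  # small-scale version of the sampling-consistency check (the full 50-config
  # version lives in the acceptance suite)
  withr::with_seed(12, {
    for (rep in 1:5) {
      logits <- rnorm(6, sd = 1.5)
      cfg <- neutral_cfg(temperature = runif(1, 0.7, 1.4),
                         top_k = sample(c(0L, 3L, 5L), 1),
                         top_p = sample(c(1, 0.9), 1),
                         repetition_penalty = sample(c(1, 1.2), 1))
      gen <- sample(6, 2)
      p <- process_logits(logits, gen, cfg)
      draws <- sample.int(6, 2e4, replace = TRUE, prob = p)
      obs <- tabulate(draws, 6) / 2e4
      se <- sqrt(p * (1 - p) / 2e4)
      expect_true(all(abs(obs - p) <= 4 * se + 1e-9))
    }
  })
})

test_that("published generation configurations carry the printed values", {
  fwd <- decode_config_folding()
  expect_true(fwd$do_sample)
  expect_equal(fwd$num_beams, 3L)
  expect_equal(fwd$temperature, 1.2)
  expect_equal(fwd$top_p, 0.95)
  expect_equal(fwd$top_k, 6L)
  expect_equal(fwd$repetition_penalty, 1.2)

  bwd <- decode_config_inverse_folding()
  expect_true(bwd$do_sample)
  expect_equal(bwd$temperature, 1.0)
  expect_equal(bwd$top_p, 0.85)
  expect_equal(bwd$top_k, 3L)
  expect_equal(bwd$repetition_penalty, 1.2)
})

test_that("decode_config validates its ranges", {
  expect_error(decode_config(temperature = 0))
  expect_error(decode_config(top_p = 0))
  expect_error(decode_config(repetition_penalty = 0.5))
  expect_error(decode_config(num_beams = 0))
})
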