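test_that("flat connectivity honours radius and excludes self-connections", {
  cm <- build_connectivity(c(PY = 50, IN = 10, TC = 10, RE = 10))
  syn <- cm$projections[["PY->PY/AMPA"]]
  # interior neuron: exactly 2R partners
  pre25 <- syn$pre[syn$post == 25]
  expect_equal(sort(pre25), setdiff(20:30, 25))
  expect_length(pre25, 10)
  # boundary neuron: truncated fan-in
  pre1 <- syn$pre[syn$post == 1]
  expect_equal(sort(pre1), 2:6)
  expect_false(any(syn$pre == syn$post))
})

test_that("a zero radius produces an empty same-population projection", {
  cm <- build_connectivity(c(PY = 20, IN = 4, TC = 4, RE = 4),
                           radii = c("PY->PY/AMPA" = 0))
  expect_equal(nrow(cm$projections[["PY->PY/AMPA"]]), 0)
})

test_that("invalid projections and radii are rejected", {
  expect_error(build_connectivity(radii = c("PY->XX/AMPA" = 3)), "unknown")
  expect_error(build_connectivity(radii = c("PY->PY/AMPA" = -1)), ">= 0")
  expect_error(build_connectivity(weights = c("nope" = 1)), "unknown")
})

test_that("cross-size projections map topographically", {
  cm <- build_connectivity(c(PY = 50, IN = 10, TC = 10, RE = 10))
  syn <- cm$projections[["TC->PY/AMPA"]]    # radius 15 in PY units
  # TC cell i projects to PY centred at round((i-1)*50/10)+1
  for (i in c(1, 5, 10)) {
    centre <- round((i - 1) * 50 / 10) + 1
    tgts <- syn$post[syn$pre == i]
    expect_true(all(abs(tgts - centre) <= 15))
  }
})

test_that("total conductance onto each target is preserved", {
  cm <- build_connectivity(c(PY = 50, IN = 10, TC = 10, RE = 10))
  for (pn in c("PY->PY/AMPA", "IN->PY/GABAA", "TC->PY/AMPA")) {
    syn <- cm$projections[[pn]]
    tot <- tapply(syn$weight, syn$post, sum)
    expect_true(all(abs(tot - cm$weights[[pn]]) < 1e-12), info = pn)
  }
})

test_that("the map is deterministic for identical configurations", {
  a <- build_connectivity(c(PY = 30, IN = 6, TC = 6, RE = 6), seed = 1)
  b <- build_connectivity(c(PY = 30, IN = 6, TC = 6, RE = 6), seed = 1)
  expect_identical(a, b)
})

test_that("default radii and weights match the network prescription", {
  r <- default_radii(); w <- default_weights()
  expect_equal(unname(r[c("PY->PY/AMPA", "PY->IN/AMPA", "IN->PY/GABAA",
                          "TC->RE/AMPA", "RE->TC/GABAB", "TC->PY/AMPA",
                          "PY->TC/AMPA")]),
               c(5, 1, 5, 8, 8, 15, 10))
  expect_equal(unname(w[c("PY->PY/AMPA", "IN->PY/GABAA", "TC->PY/AMPA",
                          "RE->TC/GABAB")]),
               c(0.24, 0.24, 0.14, 0.0025))
})
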