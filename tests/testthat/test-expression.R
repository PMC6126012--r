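test_that("GPR evaluation sums isozymes and minimises over subunits", {
  expr <- c(g1 = 10, g2 = 5, g3 = 4)
  expect_equal(reaction_expression("g1 or g2", expr), 15)
  expect_equal(reaction_expression("g1 and g2", expr), 5)
  # composition of the two rules
  expect_equal(reaction_expression("g1 and (g2 or g3)", expr), 9)
  expect_equal(reaction_expression("g1 and (g2 or g4)", expr), 5)
  # missing genes contribute zero to OR sums
  expect_equal(reaction_expression("g1 or gx", expr), 10)
  # genes absent from the table are skipped inside AND minima
  expect_equal(reaction_expression("g1 and gx", expr), 10)
  expect_error(reaction_expression(NULL, expr), "no gene association")
})

test_that("reaction expression is monotone in every gene's TPM", {
  rules <- c("g1 or g2", "g1 and g2", "g1 and (g2 or g3)")
  set.seed(11)
  for (rule in rules) {
    for (rep in 1:20) {
      expr <- stats::setNames(runif(3, 0, 100), c("g1", "g2", "g3"))
      v0 <- reaction_expression(rule, expr)
      bump <- sample(names(expr), 1)
      expr2 <- expr
      expr2[bump] <- expr2[bump] + runif(1, 0, 50)
      expect_gte(reaction_expression(rule, expr2), v0)
    }
  }
})

test_that("change calls use the 10% relative threshold", {
  expect_identical(as.vector(expression_change(100, 115)), "+")
  expect_identical(as.vector(expression_change(100, 95)), "o")
  expect_identical(as.vector(expression_change(100, 80)), "-")
  expect_identical(as.vector(expression_change(100, 110)), "o")  # boundary: not >10%
  ec <- expression_change(c(a = 0, b = 0), c(a = 5, b = 0))
  expect_identical(as.vector(ec), c("+", "o"))
  expect_identical(attr(ec, "flagged"), c(TRUE, FALSE))
})

test_that("agreement scoring matches hand arithmetic and is order invariant", {
  flux <- c(r1 = "+", r2 = "+", r3 = "-")
  expr <- c(r1 = "+", r2 = "-", r3 = "-")
  sc <- agreement_score(flux, expr, names(flux))
  expect_equal(sc$agreement, 100 * 2 / 3, tolerance = 1e-9)
  sc2 <- agreement_score(flux, expr, rev(names(flux)))
  expect_equal(sc2$agreement, sc$agreement)
  # identical calls agree fully
  full <- agreement_score(flux, flux, names(flux))
  expect_equal(full$agreement, 100)
  expect_error(agreement_score(flux, expr, character(0)), "empty")
  expect_error(agreement_score(flux, expr, "zz"), "missing")
})

scoped_calls <- function(toy) {
  sweep <- design_sweep(toy_condition(5, our = 1.0, xr_ratio = 0.94),
                        toy_condition(5, our = 1.42, xr_ratio = 0.11), 5)
  fm <- assemble_flux_matrix(toy, sweep)
  scope <- intersect(toy_scope(toy),
                     colnames(fm)[apply(abs(fm), 2, max) > 1e-6])
  flux_symbols(classify_response(fm))[scope]
}

test_that("planted agreement extremes are recovered exactly", {
  toy <- the_toy()
  fcalls <- scoped_calls(toy)
  expect_gte(length(fcalls), 8)

  score_once <- function(p, seed) {
    set.seed(seed)
    synth <- make_synthetic_expression(toy, fcalls,
                                       synthetic_expression_spec(p = p))
    e_a <- reaction_expression_profile(toy, synth$table,
                                       c("aerobic_1", "aerobic_2"),
                                       names(fcalls))
    e_l <- reaction_expression_profile(toy, synth$table,
                                       c("limited_1", "limited_2"),
                                       names(fcalls))
    agreement_score(fcalls, expression_change(e_a, e_l),
                    names(fcalls))$agreement
  }
  expect_equal(score_once(1, 1), 100)
  # p = 0 plants a different symbol for every reaction, so nothing agrees
  expect_equal(score_once(0, 2), 0)
})

test_that("a planted 75% agreement rate is recovered without bias", {
  toy <- the_toy()
  fcalls <- scoped_calls(toy)
  spec <- synthetic_expression_spec(p = 0.75)
  set.seed(20240901)
  scores <- replicate(600, {
    synth <- make_synthetic_expression(toy, fcalls, spec)
    e_a <- reaction_expression_profile(toy, synth$table,
                                       c("aerobic_1", "aerobic_2"),
                                       names(fcalls))
    e_l <- reaction_expression_profile(toy, synth$table,
                                       c("limited_1", "limited_2"),
                                       names(fcalls))
    agreement_score(fcalls, expression_change(e_a, e_l),
                    names(fcalls))$agreement
  })
  expect_lt(abs(mean(scores) - 75), 2)
  # and the calls actually realised match what was planted
  set.seed(4)
  synth <- make_synthetic_expression(toy, fcalls, spec)
  e_a <- reaction_expression_profile(toy, synth$table,
                                     c("aerobic_1", "aerobic_2"),
                                     names(fcalls))
  e_l <- reaction_expression_profile(toy, synth$table,
                                     c("limited_1", "limited_2"),
                                     names(fcalls))
  expect_identical(unname(expression_change(e_a, e_l)[names(fcalls)]),
                   unname(synth$planted[names(fcalls)]))
})

test_that("expression tables round-trip through TSV and reject negatives", {
  toy <- the_toy()
  fcalls <- scoped_calls(toy)
  set.seed(5)
  synth <- make_synthetic_expression(toy, fcalls)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(synth$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  back <- read_expression_tsv(path)
  expect_identical(back$gene, synth$table$gene)
  expect_equal(back$aerobic_1, synth$table$aerobic_1, tolerance = 1e-9)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1", "g1\t-3"), bad)
  expect_error(read_expression_tsv(bad), "TPM")
})
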