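test_that("TSV chain network yields the expected stoichiometry", {
  net <- make_toy_network("chain")
  expect_equal(net$reaction_ids, c("R1", "R2", "R3"))
  expect_equal(net$metabolite_ids, c("A", "B"))
  expect_equal(unname(net$S), rbind(c(1, -1, 0), c(0, 1, -1)))
  expect_false(any(net$reversible))
  expect_equal(net$lb, c(0, 0, 0))
  expect_equal(net$ub, rep(1000, 3))
})

test_that("TSV round trip preserves the network", {
  for (name in c("chain", "diamond", "mini_ccm")) {
    net <- make_toy_network(name)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_network_tsv(net, path)
    net2 <- read_network_tsv(path)
    expect_equal(net2$S[net$metabolite_ids, ], net$S)
    expect_equal(net2$reversible, net$reversible)
    expect_equal(net2$lb, net$lb)
    expect_equal(net2$ub, net$ub)
    expect_equal(net2$subsystem, net$subsystem)
    for (k in seq_along(net$gene_rules)) {
      r1 <- net$gene_rules[[k]]; r2 <- net2$gene_rules[[k]]
      expect_equal(is.null(r1), is.null(r2))
      if (!is.null(r1))
        expect_equal(deparse_gene_rule(r2), deparse_gene_rule(r1))
    }
  }
})

test_that("TSV defaults: reversible flag implies lb = -1000", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tequation\treversible",
               "R1\tA <-> B\ttrue",
               "R2\t-> A\tfalse",
               "R3\tB ->\tfalse"), path)
  net <- read_network_tsv(path)
  expect_equal(net$lb, c(-1000, 0, 0))
  expect_equal(net$ub, rep(1000, 3))
})

test_that("malformed TSV lines and invalid networks are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tequation", "R1\tA + B"), path)
  expect_error(read_network_tsv(path), "malformed")
  expect_error(metabolic_network(c("R1", "R1"), "A", matrix(1, 1, 2)),
               "duplicate")
  expect_error(metabolic_network(character(0), character(0),
                                 matrix(0, 0, 0)), "empty")
  expect_error(metabolic_network("R1", "A", matrix(1, 1, 1),
                                 reversible = FALSE, lb = -1, ub = 1),
               "irreversible")
})

test_that("SBML chain with boundary species matches the TSV network", {
  net <- make_toy_network("chain")
  path <- withr::local_tempfile(fileext = ".xml")
  write_network_sbml(net, path, external = c("SRC", "SNK"))
  net2 <- read_network_sbml(path)
  expect_equal(net2$metabolite_ids, c("A", "B"))
  expect_equal(net2$S, net$S)
  expect_equal(net2$reversible, net$reversible)
  expect_equal(net2$lb, net$lb)
  expect_equal(net2$ub, net$ub)
})

test_that("SBML fbc gene association parses to the expected AST", {
  net <- make_toy_network("chain")
  net$gene_rules[[2]] <- parse_gene_rule("g1 or g2")
  path <- withr::local_tempfile(fileext = ".xml")
  write_network_sbml(net, path)
  net2 <- read_network_sbml(path)
  expect_equal(net2$gene_rules[[2]],
               list(op = "or", children = list(list(op = "leaf", gene = "g1"),
                                               list(op = "leaf", gene = "g2"))))
  expect_null(net2$gene_rules[[1]])
})

test_that("split_reversible duplicates reversible columns with negation", {
  net <- make_toy_network("diamond")   # R3 reversible
  sp <- split_reversible(net)
  expect_equal(ncol(sp$network$S), 7)
  r3 <- which(net$reaction_ids == "R3")
  f <- sp$mapping$forward[r3]; b <- sp$mapping$backward[r3]
  expect_equal(sp$network$S[, b], -sp$network$S[, f])
  expect_false(any(sp$network$reversible))

  chain <- make_toy_network("chain")
  sp2 <- split_reversible(chain)
  expect_equal(sp2$network$S, chain$S)
  expect_equal(sp2$mapping$forward, 1:3)
  expect_true(all(is.na(sp2$mapping$backward)))
})

test_that("recombined split fluxes reproduce split-space balances", {
  net <- make_toy_network("diamond")
  sp <- split_reversible(net)
  set.seed(11)
  for (rep in 1:20) {
    v <- runif(ncol(sp$network$S))
    expect_equal(drop(net$S %*% recombine_fluxes(v, sp$mapping)),
                 drop(sp$network$S %*% v), tolerance = 1e-12)
  }
})

test_that("subsystem selection returns sorted unique indices", {
  net <- make_toy_network("mini_ccm")
  expect_equal(subsystem_columns(net, net$reaction_ids),
               seq_along(net$reaction_ids))
  expect_equal(subsystem_columns(net, "tca"),
               which(net$subsystem == "tca"))
  expect_error(subsystem_columns(net, "golgi"), "matches no")
})

test_that("a generated 500-reaction fixture with 166 labelled reactions selects them all", {
  path <- withr::local_tempfile(fileext = ".tsv")
  set.seed(9)
  labelled <- sort(sample(500, 166))
  rows <- vapply(1:500, function(i) {
    sub <- if (i %in% labelled) "mitochondrion" else "cytosol"
    sprintf("RX%03d\t-> M%03d\tfalse\t\t\t%s\t", i, i, sub)
  }, character(1))
  writeLines(c("reaction_id\tequation\treversible\tlb\tub\tsubsystem\tgene_rule",
               rows), path)
  net <- read_network_tsv(path)
  expect_length(subsystem_columns(net, "mitochondrion"), 166)
  expect_equal(subsystem_columns(net, "mitochondrion"), labelled)
})

test_that("S %*% w matches an explicit double loop on random inputs", {
  net <- make_toy_network("mini_ccm")
  set.seed(4)
  for (rep in 1:10) {
    w <- rnorm(ncol(net$S))
    slow <- vapply(seq_len(nrow(net$S)), function(m)
      sum(vapply(seq_len(ncol(net$S)), function(r) net$S[m, r] * w[r],
                 numeric(1))), numeric(1))
    expect_equal(drop(net$S %*% w), slow, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})
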