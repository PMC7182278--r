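test_that("reaction-file parsing handles identity, condensation and atom-free species", {
  net <- parse_network(c("@external M",
                         "r16\tM[ab] -> N[ab]\t0"))
  expect_s3_class(net, "flux_network")
  expect_equal(sort(net$metabolites$id), c("M", "N"))
  expect_equal(net$reactions$r16$substrates[[1]]$atoms, c("a", "b"))
  expect_equal(net$reactions$r16$products[[1]]$atoms, c("a", "b"))
  expect_false(net$reactions$r16$reversible)

  net2 <- parse_network(c("@external G K",
                          "r11\tG[ab] + K[cd] -> H[abcd]\t0"))
  h <- net2$reactions$r11$products[[1]]
  expect_equal(h$atoms, c("a", "b", "c", "d"))
  expect_equal(met_n_atoms <- net2$metabolites$n_atoms[net2$metabolites$id == "H"], 4L)

  net3 <- parse_network(c("@external S ATP",
                          "rk\tS[ab] + 2 ATP -> T[ab]\t0"))
  expect_equal(net3$metabolites$n_atoms[net3$metabolites$id == "ATP"], 0L)
  expect_equal(net3$reactions$rk$substrates[[2]]$coef, 2)
})

test_that("parse errors are informative and carry line numbers", {
  expect_error(parse_network("rX\tA[ab] -> B[abc]\t0"),
               "no substrate source")
  expect_error(parse_network(c("@external A", "r1\tA[ab] -> B[ab]\t0",
                               "r1\tA[ab] -> B[ab]\t0")),
               "duplicate reaction id")
  expect_error(parse_network(c("@external A",
                               "r1\tA[ab] -> B[ab]\t0",
                               "r2\tB[abc] -> C[abc]\t0")),
               "inconsistent atom count")
  expect_error(parse_network(c("@external A", "r1 A[ab] B[ab]")),
               "line 2")
  expect_error(parse_network(c("@external A", "r1\tA[ab] -> B[a]\t0")),
               "do not appear in any product")
  expect_error(parse_network(c("r1\tA[ab] -> B[ab]\t0")),
               "never produced")
  expect_error(parse_network(c("@external A", "r1\t2 A[ab] -> B[ab] + C\t0")),
               "coefficient 1")
})

test_that("write_network round-trips networks including reversible flags", {
  for (net in list(example_network(), prenyl_network(),
                   parse_network(c("@external X", "r\tX[a] -> Y[a]\t1")))) {
    back <- parse_network(write_network(net))
    expect_equal(write_network(back), write_network(net))
    expect_equal(back$metabolites, net$metabolites)
    expect_equal(names(back$reactions), names(net$reactions))
    expect_equal(vapply(back$reactions, `[[`, TRUE, "reversible"),
                 vapply(net$reactions, `[[`, TRUE, "reversible"))
  }
})

test_that("atom labels are conserved in every fixture reaction", {
  for (net in list(example_network(), prenyl_network())) {
    for (rxn in net$reactions) {
      subs <- sort(unlist(lapply(rxn$substrates, `[[`, "atoms")))
      prods <- sort(unlist(lapply(rxn$products, `[[`, "atoms")))
      expect_identical(subs, prods)
    }
  }
})

test_that("split_reversible mirrors reversible reactions and is idempotent", {
  net <- example_network()
  split <- split_reversible(net)
  expect_false(any(vapply(split$reactions, `[[`, TRUE, "reversible")))
  expect_equal(length(split$reactions), length(net$reactions) + 1L)
  expect_equal(split$reactions$r6_fwd$substrates[[1]]$met, "B")
  expect_equal(split$reactions$r6_rev$substrates[[1]]$met, "C")
  expect_equal(split$reactions$r6_rev$products[[1]]$met, "B")
  # atom map mirrored
  expect_equal(split$reactions$r6_rev$substrates[[1]]$atoms,
               split$reactions$r6_fwd$products[[1]]$atoms)
  expect_equal(split$metabolites, net$metabolites)
  expect_equal(write_network(split_reversible(split)), write_network(split))
  # networks without reversible reactions are untouched
  expect_equal(write_network(split_reversible(prenyl_network())),
               write_network(prenyl_network()))
})

test_that("producers_of reports forward producers and reverse directions", {
  net <- example_network()
  expect_equal(producers_of(net, "F"), c("r4", "r9"))
  expect_equal(producers_of(net, "A"), "r2")
  expect_equal(producers_of(net, "X_out"), character(0))
  # reversible r6 produces both B and C
  expect_true("r6" %in% producers_of(net, "B"))
  expect_true("r6" %in% producers_of(net, "C"))
  expect_error(producers_of(net, "ZZZ"), "unknown metabolite")
})
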