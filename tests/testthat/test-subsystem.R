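test_that("minimal subsystems contain producers, inputs and a sink", {
  net <- example_network()
  sH <- minimal_subsystem(net, "H")
  expect_equal(names(sH$reactions), "r11")
  expect_equal(sH$local_inputs, c("G", "K"))
  expect_equal(sH$intermediates, "H")
  expect_equal(sH$sinks$id, "sink_H")

  sA <- minimal_subsystem(net, "A")
  expect_equal(names(sA$reactions), "r2")
  expect_equal(sA$local_inputs, "X_in")

  # reversible r6 contributes its producing direction to each side
  sC <- minimal_subsystem(net, "C")
  expect_true("r6_fwd" %in% names(sC$reactions))
  sB <- minimal_subsystem(net, "B")
  expect_true(all(c("r3", "r6_rev") %in% names(sB$reactions)))

  expect_error(minimal_subsystem(net, "X_out"), "external")
  expect_error(minimal_subsystem(net, "nope"), "unknown")
})

test_that("decomposition yields one subsystem per metabolic intermediate", {
  subs <- decompose_network(example_network())
  expect_length(subs, 17L)

  chain <- parse_network(c("@external X_out",
                           "r1\tX_out[a] -> A[a]\t0",
                           "r2\tA[a] -> B[a]\t0",
                           "r3\tB[a] -> C[a]\t0"))
  expect_length(decompose_network(chain), 3L)

  for (seed in 1:8) {
    n <- 1 + (seed %% 5)
    truth <- random_linear_pathway(n, seed = seed)
    expect_length(decompose_network(truth$network), n)
  }
})

test_that("every subsystem carries the full producer set of each intermediate", {
  net <- example_network()
  split <- split_reversible(net)
  subs <- decompose_network(net)
  merged <- merge_subsystems(merge_subsystems(subs$S_N, subs$S_O), subs$S_F)
  for (s in c(subs, list(merged))) {
    for (y in s$intermediates) {
      expect_true(all(producers_of(split, y) %in% names(s$reactions)),
                  label = sprintf("%s producers of %s", s$name, y))
    }
  }
})

test_that("merging internalizes the shared metabolite", {
  subs <- decompose_network(example_network())
  sNO <- merge_subsystems(subs$S_N, subs$S_O)
  expect_equal(sNO$intermediates, c("N", "O"))
  expect_false("N" %in% sNO$local_inputs)

  sFNO <- merge_subsystems(sNO, subs$S_F)
  expect_equal(sFNO$intermediates, c("F", "N", "O"))
  expect_equal(sFNO$local_inputs, c("A", "E", "M"))
  expect_equal(sort(names(sFNO$reactions)),
               sort(c("r4", "r9", "r16", "r17", "r18")))

  expect_error(merge_subsystems(subs$S_A, subs$S_N), "share no metabolite")
})

test_that("merge order does not matter on connected families", {
  subs <- decompose_network(example_network())
  fam <- list(subs$S_G, subs$S_H, subs$S_K, subs$S_I, subs$S_J)
  m1 <- Reduce(merge_subsystems, fam)
  m2 <- Reduce(merge_subsystems, rev(fam))
  m3 <- merge_subsystems(merge_subsystems(subs$S_I, subs$S_J),
                         Reduce(merge_subsystems,
                                list(subs$S_K, subs$S_H, subs$S_G)))
  for (m in list(m2, m3)) {
    expect_equal(m$name, m1$name)
    expect_equal(names(m$reactions), names(m1$reactions))
    expect_equal(m$intermediates, m1$intermediates)
    expect_equal(m$local_inputs, m1$local_inputs)
  }
})

test_that("sink fluxes balance production against consumption", {
  truth <- example_truth_cached
  subs <- decompose_network(truth$network)
  sF <- subs$S_F
  bal <- sink_fluxes(sF, truth$fluxes[names(sF$reactions)])
  expect_equal(bal$flux[bal$substrate == "F"],
               unname(truth$fluxes["r4"] + truth$fluxes["r9"]))
  # in a merged subsystem, internal consumption reduces the sink
  sGH <- merge_subsystems(subs$S_G, subs$S_H)
  bal2 <- sink_fluxes(sGH, truth$fluxes[names(sGH$reactions)])
  expect_equal(bal2$flux[bal2$substrate == "G"],
               unname(truth$fluxes["r10"] - truth$fluxes["r11"]))
  # at the true fluxes, every sink of the full network is non-negative
  full <- subflux:::network_subsystem(truth$network)
  expect_true(all(sink_fluxes(full, truth$fluxes)$flux > -1e-9))
})

test_that("pathway enumeration returns deterministic connected unions", {
  net <- example_network()
  single <- enumerate_pathway_subsystems(net, "r16")
  expect_length(single, 1L)
  expect_equal(single[[1]]$name, "S_N")

  two <- enumerate_pathway_subsystems(net, c("r15", "r16"))
  expect_equal(vapply(two, `[[`, "", "name"), c("S_M", "S_N", "S_MN"))

  path <- enumerate_pathway_subsystems(net, paste0("r", 10:16))
  nms <- vapply(path, `[[`, "", "name")
  expect_true(all(c("S_G", "S_H", "S_K", "S_L", "S_M", "S_N", "S_IJ",
                    "S_GH", "S_MN", "S_GHIJKLM") %in% nms))
  # deterministic: same result on a second call
  path2 <- enumerate_pathway_subsystems(net, paste0("r", 10:16))
  expect_equal(nms, vapply(path2, `[[`, "", "name"))
  # ordering: reaction-count non-decreasing
  sizes <- vapply(path, function(s) length(s$reactions), 0L)
  expect_true(all(diff(sizes) >= 0))

  expect_error(enumerate_pathway_subsystems(net, character(0)), "empty")
  expect_error(enumerate_pathway_subsystems(net, c("r2", "r16")),
               "connected")
})
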