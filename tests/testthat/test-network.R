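test_that("network construction validates weights and shapes", {
  expect_error(genetic_network(matrix(2), matrix(0)), "-1, 0, 1")
  expect_error(genetic_network(matrix(0, 2, 2), matrix(0, 1, 1)), "square")
  net <- genetic_network(matrix(c(1, 0, 0, -1), 2, 2),
                         matrix(0, 2, 2))
  expect_s3_class(net, "genetic_network")
  expect_equal(net$n_genes, 2)
})

test_that("canonical networks match their defining edge structure", {
  o1 <- canonical_networks("O1")
  expect_equal(o1$w_intra, matrix(1))
  expect_equal(o1$w_inter, matrix(-1))
  expect_equal(o1$rule_variant, "threshold_zero")

  t1 <- canonical_networks("T1")
  expect_equal(t1$w_intra, matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE))
  expect_equal(t1$w_inter, matrix(c(-1, 0, 1, -1), 2, 2, byrow = TRUE))

  t1p <- canonical_networks("T1'")
  expect_equal(t1p$w_intra, permute_genes(t1)$w_intra)
  expect_equal(t1p$w_inter, permute_genes(t1)$w_inter)

  o2 <- canonical_networks("O2")
  expect_equal(o2$rule_variant, "biased_plus_one")
  expect_error(canonical_networks("nope"), "unknown")
})

test_that("network ids are a bijection onto the enumeration", {
  for (id in enumerate_networks(1))
    expect_equal(network_id(decode_network(id, 1)), id)
  set.seed(1)
  for (id in sample(enumerate_networks(2), 50))
    expect_equal(network_id(decode_network(id, 2)), id)
  expect_error(decode_network(9, 1), "out of range")
  expect_length(enumerate_networks(1), 9)
  expect_length(enumerate_networks(2), 6561)
})

test_that("network serialization round-trips losslessly", {
  path <- withr::local_tempfile(fileext = ".json")
  for (nm in c("O1", "O2", "T1", "T5")) {
    net <- canonical_networks(nm)
    write_network(net, path)
    back <- read_network(path)
    expect_equal(back$w_intra, net$w_intra)
    expect_equal(back$w_inter, net$w_inter)
    expect_equal(back$rule_variant, net$rule_variant)
    expect_equal(back$name, nm)
  }
})

test_that("updates follow the weighted-sum step rule with tie-holding", {
  o1 <- canonical_networks("O1")
  all_on <- tissue_state(matrix(1, 4, 1))
  # interior cell: h = 1 - 2 = -1 -> switches off
  expect_equal(update_gene(o1, all_on, cell_index = 2, gene_index = 1), 0)
  # edge cell: h = 1 - 1 = 0 -> holds its current ON state
  expect_equal(update_gene(o1, all_on, cell_index = 1, gene_index = 1), 1)
  # the all-zero tissue is a fixed point of every threshold-zero network
  zero <- tissue_state(matrix(0, 4, 1))
  for (id in enumerate_networks(1)) {
    net <- decode_network(id, 1)
    expect_equal(update_tissue(net, zero)$S, zero$S)
  }
  expect_error(update_gene(o1, all_on, cell_index = 9, gene_index = 1),
               "out of range")
  expect_error(update_tissue(o1, all_on, contacts = contact_matrix(3)),
               "does not match")
})

test_that("tissue update reproduces the worked single- and two-gene patterns", {
  o1 <- canonical_networks("O1")
  expect_equal(update_tissue(o1, tissue_state(matrix(1, 4, 1)))$S[, 1],
               c(1, 0, 0, 1))
  # two ON cells hold each other (h = 0 everywhere)
  expect_equal(update_tissue(o1, tissue_state(matrix(1, 2, 1)))$S[, 1],
               c(1, 1))

  t1 <- canonical_networks("T1")
  four_blue <- tissue_state(matrix(1, 4, 2))
  expect_equal(tissue_labels(update_tissue(t1, four_blue)),
               c("B", "R", "R", "B"))
  eight <- tissue_state(rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1),
                              c(0, 1), c(0, 1), c(1, 0), c(1, 0)))
  expect_equal(tissue_labels(update_tissue(t1, eight)),
               c("B", "G", "R", "Y", "Y", "R", "G", "B"))
})

test_that("matrix update agrees with the literal brute-force oracle", {
  # full enumeration for one gene, sampled networks x states for two
  for (id in enumerate_networks(1)) {
    net <- decode_network(id, 1)
    for (m in 1:4) for (S in all_states(m, 1)) {
      expect_equal(update_tissue(net, tissue_state(S))$S,
                   oracle_update(S, net$w_intra, net$w_inter))
    }
  }
  set.seed(42)
  states2 <- all_states(3, 2)
  for (id in sample(enumerate_networks(2), 40)) {
    for (rule in c("threshold_zero", "biased_plus_one")) {
      net <- decode_network(id, 2, rule)
      bias <- if (rule == "biased_plus_one") 1 else 0
      for (S in states2[sample(length(states2), 8)]) {
        expect_equal(update_tissue(net, tissue_state(S))$S,
                     oracle_update(S, net$w_intra, net$w_inter, bias))
      }
    }
  }
})

test_that("update commutes with left-right mirror reversal", {
  set.seed(7)
  for (id in sample(enumerate_networks(2), 30)) {
    net <- decode_network(id, 2)
    S <- matrix(rbinom(10, 1, 0.5), 5, 2)
    fwd <- update_tissue(net, tissue_state(S))$S
    rev_in <- S[5:1, , drop = FALSE]
    bwd <- update_tissue(net, tissue_state(rev_in))$S
    expect_equal(bwd[5:1, , drop = FALSE], fwd)
  }
})

test_that("concatenated matrix holds own states then neighbour sums", {
  t4 <- tissue_state(matrix(1, 4, 1))
  expect_equal(concatenated_matrix(t4),
               cbind(c(1, 1, 1, 1), c(1, 2, 2, 1)))
  single <- tissue_state(matrix(c(1, 0), 1, 2))
  expect_equal(concatenated_matrix(single), cbind(1, 0, 0, 0))
  eight <- tissue_state(rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1),
                              c(0, 1), c(0, 1), c(1, 0), c(1, 0)))
  rows <- apply(concatenated_matrix(eight), 1, paste, collapse = ",")
  expect_length(unique(rows), 4)
})

test_that("tissue snapshots round-trip through the TSV format", {
  tis <- tissue_state(rbind(c(1, 0), c(0, 1), c(1, 1)), generation = 3,
                      lineage = c(4, 5, 6))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tissue(tis, path)
  back <- read_tissue(path)
  expect_equal(back$S, tis$S, ignore_attr = TRUE)
  expect_equal(back$generation, 3L)
  expect_equal(back$lineage, c(4L, 5L, 6L))
})
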