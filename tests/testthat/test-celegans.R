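test_that("embryo snapshots validate their contact graph", {
  expect_error(embryo_snapshot(c("A", "A"), c("a", "a"),
                               rbind(c("A", "A"))), "unique")
  expect_error(embryo_snapshot(c("A", "B"), c("a", "b"),
                               rbind(c("A", "C"))), "not in the cell list")
  sn <- celegans_four_cell()
  expect_setequal(sn$cells, c("ABa", "ABp", "EMS", "P2"))
  # P2 touches ABp but not ABa
  nb_p2 <- divdec:::neighbour_names(sn, "P2")
  expect_true("ABp" %in% nb_p2)
  expect_false("ABa" %in% nb_p2)
})

test_that("the 4-cell stage holds 1.5 bit that the Notch event lifts to 2.0", {
  before <- embryo_information_trace(celegans_four_cell())
  expect_equal(before$pi_bits, 1.5)
  expect_equal(before$potential_bits, 2.0)
  after <- embryo_information_trace(celegans_four_cell(after_notch = TRUE))
  expect_equal(after$pi_bits, 2.0)

  single <- embryo_snapshot("egg", "zygote", matrix(character(0), 0, 2))
  tr <- embryo_information_trace(single)
  expect_equal(tr$pi_bits, 0)
  expect_equal(tr$potential_bits, 0)
})

test_that("embryo information agrees with the generic tissue code path", {
  # a line-shaped embryo maps onto the 1-D tissue machinery: identical PI
  # and potential information from both code paths
  states <- c("g", "r", "r", "g")
  sn <- embryo_snapshot(paste0("c", 1:4), states,
                        rbind(c("c1", "c2"), c("c2", "c3"), c("c3", "c4")))
  tr <- embryo_information_trace(sn)
  tis <- tissue_state(rbind(c(1, 0), c(0, 1), c(0, 1), c(1, 0)))
  expect_equal(tr$pi_bits, positional_information(tis))
  expect_equal(tr$potential_bits, potential_information(tis))
})

test_that("fate rules fire on inherited state and contact jointly", {
  # 4-cell: absence of P2 contact converts ab -> aba in ABa only
  r4 <- list(from_state = "ab", contact_state = "p2", to_state = "aba",
             require_contact = FALSE)
  chk <- contact_rule_check(celegans_four_cell(),
                            celegans_four_cell(after_notch = TRUE), r4)
  expect_true(all(chk$match))
  expect_equal(chk$predicted[chk$cell == "ABa"], "aba")
  expect_equal(chk$predicted[chk$cell == "ABp"], "ab")

  # 12-cell: C contact converts aba -> abarp in ABarp, but ABpra, in the
  # same contact situation with a different pedigree, stays put
  r12 <- list(from_state = "aba", contact_state = "c", to_state = "abarp")
  chk12 <- contact_rule_check(celegans_twelve_cell(),
                              celegans_twelve_cell(after_contact = TRUE),
                              r12)
  expect_true(chk12$match[chk12$cell == "ABarp"])
  expect_equal(chk12$predicted[chk12$cell == "ABarp"], "abarp")
  expect_true(chk12$has_contact[chk12$cell == "ABpra"])
  expect_equal(chk12$predicted[chk12$cell == "ABpra"], "ab")
  expect_true(chk12$match[chk12$cell == "ABpra"])

  # an impossible contact requirement fires nowhere
  r_none <- list(from_state = "ab", contact_state = "zz", to_state = "x")
  chk_none <- contact_rule_check(celegans_four_cell(), celegans_four_cell(),
                                 r_none)
  expect_true(all(chk_none$predicted == chk_none$state))
})

test_that("embryo tables load into snapshots and round-trip the fixtures", {
  dir <- withr::local_tempdir()
  generate_fixtures(dir)
  snaps <- load_embryo_tables(file.path(dir, "celegans_4cell_expression.tsv"),
                              file.path(dir, "celegans_4cell_contacts.tsv"))
  expect_length(snaps, 1)
  expect_equal(embryo_information_trace(snaps[[1]])$pi_bits, 1.5)

  snaps12 <- load_embryo_tables(
    file.path(dir, "celegans_12cell_expression.tsv"),
    file.path(dir, "celegans_12cell_contacts.tsv"))
  sn <- snaps12[[1]]
  expect_true("MS" %in% divdec:::neighbour_names(sn, "ABalp"))
  expect_true("C" %in% divdec:::neighbour_names(sn, "ABarp"))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("cell\tstage\tstate", empty)
  expect_error(load_embryo_tables(empty, empty), "empty")

  # contacts naming unknown cells are rejected with the offending names
  expr_p <- withr::local_tempfile(fileext = ".tsv")
  ct_p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cell\tstage\tstate", "A\ts1\tx", "B\ts1\ty"), expr_p)
  writeLines(c("stage\tcell_a\tcell_b", "s1\tA\tZZ"), ct_p)
  expect_error(load_embryo_tables(expr_p, ct_p), "ZZ")
})
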