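# A deterministic two-chain structure for selection/interface tests:
# chain A = 30-residue micelle ball at the origin, chain B = 10 residues
# offset along x by `offset` Angstrom.
two_chain_ea <- function(offset = 30, seed = 8) {
  a <- make_micelle(30, seed = seed, radius = 10)
  b <- make_micelle(10, seed = seed + 1, radius = 5)
  data.frame(
    chain = rep(c("A", "B"), c(30, 10)),
    resno = c(1:30, 1:10), insert = "",
    resid = NA_character_,
    label = c(paste0("A:", 1:30), paste0("B:", 1:10)),
    x = c(a$points[, 1], b$points[, 1] + offset),
    y = c(a$points[, 2], b$points[, 2]),
    z = c(a$points[, 3], b$points[, 3]),
    h = c(a$h, b$h), stringsAsFactors = FALSE
  )
}

test_that("component mode on the full parent reproduces individual mode", {
  ea <- two_chain_ea()
  parent <- unit_selection("A", chains = "A")
  ind <- analyze_individual(ea, parent)
  comp <- analyze_component(ea, parent, unit_selection("A-sub", chains = "A"))
  expect_equal(comp$rd, ind$rd)
  expect_equal(comp$k, ind$k)
  expect_equal(comp$n_residues, ind$n_residues)
})

test_that("restricted profiles conserve the parent's observed mass", {
  ea <- two_chain_ea(offset = 12)  # chains interact
  whole <- unit_selection("all", chains = c("A", "B"))
  fit <- attr(analyze_individual(ea, whole), "fit")
  idx_a <- seq_len(30)
  # the two chain restrictions partition the parent's O exactly
  expect_equal(sum(fit$profiles$o[idx_a]) + sum(fit$profiles$o[-idx_a]), 1)
  ca <- attr(analyze_component(ea, whole, unit_selection("A", chains = "A")), "fit")
  expect_equal(ca$profiles$o,
               fit$profiles$o[idx_a] / sum(fit$profiles$o[idx_a]))
  expect_equal(ca$profiles$t,
               fit$profiles$t[idx_a] / sum(fit$profiles$t[idx_a]))
})

test_that("selections resolve ranges and reject escape from the parent", {
  ea <- two_chain_ea()
  sel <- unit_selection("head", ranges = data.frame(chain = "A", start = 1, end = 10))
  rec <- analyze_individual(ea, sel)
  expect_equal(rec$n_residues, 10)
  expect_error(
    analyze_component(ea, unit_selection("A", chains = "A"),
                      unit_selection("B!", chains = "B")),
    "not contained")
  expect_error(unit_selection("bad"), "needs chains")
  expect_error(unit_selection("bad", ranges = data.frame(chain = "A", start = 5, end = 2)),
               "end < start")
})

test_that("interface partition is exhaustive, disjoint, boundary-inclusive", {
  ea <- two_chain_ea(offset = 100)   # partner far away: no contacts
  target <- unit_selection("A", chains = "A")
  partners <- unit_selection("B", chains = "B")
  iface <- interface_residues(ea, target, partners)
  expect_length(iface$pp, 30)
  expect_false(any(iface$pp))

  # exactly at the threshold counts as contact
  ea2 <- data.frame(chain = c("A", "A", "A", "B"), resno = c(1, 2, 3, 1),
                    insert = "", resid = NA, label = c("A:1", "A:2", "A:3", "B:1"),
                    x = c(0, 5, 40, 14), y = 0, z = 0, h = 0.5)
  if2 <- interface_residues(ea2, unit_selection("A", chains = "A"),
                            unit_selection("B", chains = "B"))
  expect_equal(if2$pp, c(FALSE, TRUE, FALSE))  # |5-14| = 9 = threshold

  # constructed fixture: only residue 3 within reach of the partner
  ea3 <- two_chain_ea(offset = 100)
  ea3 <- rbind(ea3, data.frame(chain = "C", resno = 1, insert = "", resid = NA,
                               label = "C:1",
                               x = ea3$x[3] + 5, y = ea3$y[3], z = ea3$z[3],
                               h = 0.5))
  if3 <- interface_residues(ea3, unit_selection("A", chains = "A"),
                            unit_selection("C", chains = "C"))
  near <- which(sqrt((ea3$x[1:30] - ea3$x[41])^2 + (ea3$y[1:30] - ea3$y[41])^2 +
                       (ea3$z[1:30] - ea3$z[41])^2) <= 9)
  expect_true(3 %in% near)
  expect_equal(which(if3$pp), near)
})

test_that("interface analysis fills rd_pp/rd_nopp only when classes exist", {
  ea <- two_chain_ea(offset = 12)
  target <- unit_selection("A", chains = "A")
  partners <- unit_selection("B", chains = "B")
  rec <- analyze_with_interface(ea, target, partners)
  expect_false(is.na(rec$rd_pp))
  expect_false(is.na(rec$rd_nopp))
  expect_true(rec$rd >= 0 && rec$rd <= 1)

  # no partners: plain record
  rec0 <- analyze_with_interface(ea, target, NULL)
  expect_true(is.na(rec0$rd_pp) && is.na(rec0$rd_nopp))
  expect_equal(rec0$rd, rec$rd)

  # partner out of reach: PP empty, rd_pp absent, rd_nopp equals rd of the
  # full unit only if all residues are no-PP and restriction is identity
  far <- two_chain_ea(offset = 200)
  recf <- analyze_with_interface(far, target, partners)
  expect_true(is.na(recf$rd_pp))
  expect_equal(recf$rd_nopp, recf$rd)
})

test_that("complex analysis emits the full row scheme", {
  ea <- two_chain_ea(offset = 12)
  part <- unit_selection("head-A", ranges = data.frame(chain = "A", start = 1, end = 15))
  recs <- analyze_complex(ea, partitions = list(part))
  # 1 complex + (component + individual) per chain + 1 partition
  expect_equal(nrow(recs), 1 + 2 * 2 + 1)
  expect_equal(recs$mode[1], "individual")
  expect_setequal(recs$label[2:5],
                  c("chain_A_in_complex", "chain_A_individual",
                    "chain_B_in_complex", "chain_B_individual"))

  # single-chain "complex": complex row equals the chain's individual row
  one <- ea[ea$chain == "A", ]
  r1 <- analyze_complex(one)
  expect_equal(r1$rd[1], r1$rd[3])
  expect_equal(r1$k[1], r1$k[3])
  # partition covering everything reproduces the complex row
  all_part <- unit_selection("everything", chains = c("A", "B"))
  r2 <- analyze_complex(ea, partitions = list(all_part))
  expect_equal(r2$rd[nrow(r2)], r2$rd[1])
})

test_that("records carry provenance and repeat runs are identical", {
  ea <- two_chain_ea()
  p <- fod_params()
  a <- analyze_individual(ea, unit_selection("A", chains = "A"), p)
  b <- analyze_individual(ea, unit_selection("A", chains = "A"), p)
  attr(a, "fit") <- attr(b, "fit") <- NULL
  expect_identical(a, b)
  expect_equal(a$scale, "kyte_doolittle")
  expect_equal(a$cutoff, 9)
  expect_equal(a$sigma_rule, "extent3")
})
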