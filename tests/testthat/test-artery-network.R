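test_that("the parameter set carries 33 segments with valid terminals", {
  ps <- artery_parameter_set("scenario1")
  expect_equal(nrow(ps$segments), 22L)
  expect_equal(nrow(ps$terminals), 11L)
  expect_true(all(ps$segments$R_SI > 0 & ps$segments$L_SI > 0 &
                    ps$segments$C_SI > 0))
  # removing a segment is a build error naming it
  broken <- ps
  broken$segments <- broken$segments[broken$segments$name != "basilar", ]
  expect_error(validate_parameter_set(broken), "basilar")
  ps2 <- artery_parameter_set("scenario2")
  expect_equal(nrow(ps2$segments), 22L)
  expect_false(isTRUE(all.equal(ps$segments$R_SI, ps2$segments$R_SI)))
})

test_that("the network build audit matches the declared tables", {
  ps <- artery_parameter_set("scenario1")
  net <- build_network(40, ps)
  expect_silent(validate_circuit(net))
  kinds <- vapply(net$elements, `[[`, "", "kind")
  # one series RL branch per segment, two half-capacitors per segment,
  # one terminal capacitor + Rp + Rd per outlet, one inflow, 7 sources
  expect_equal(sum(kinds == "inductor"), 22L)
  expect_equal(sum(kinds == "capacitor"), 2L * 22L + 11L)
  expect_equal(sum(kinds == "resistor"), 2L * 11L)
  expect_equal(sum(kinds == "flow_source"), 1L)
  expect_equal(sum(kinds == "pressure_source"), 1L + 6L)
})

test_that("builds at different ages differ only in the aorta and CCA laws", {
  n20 <- build_network(20)
  n60 <- build_network(60)
  ids <- vapply(n20$elements, `[[`, "", "id")
  for (i in seq_along(ids)) {
    e20 <- n20$elements[[i]]; e60 <- n60$elements[[i]]
    if (e20$kind == "capacitor" && e20$law$type %in% c("aorta", "cca")) {
      expect_equal(e60$law$age, 60)
    } else {
      expect_identical(e20[setdiff(names(e20), "law")],
                       e60[setdiff(names(e60), "law")])
      if (e20$kind == "capacitor") expect_identical(e20$law, e60$law)
    }
  }
})

reachable_from <- function(seg, roots, drop = character()) {
  seg <- seg[!seg$name %in% drop, ]
  edges <- rbind(cbind(seg$proximal_node, seg$distal_node),
                 cbind(seg$distal_node, seg$proximal_node))
  seen <- roots
  repeat {
    nxt <- unique(edges[edges[, 1] %in% seen, 2])
    nxt <- setdiff(nxt, seen)
    if (!length(nxt)) break
    seen <- c(seen, nxt)
  }
  seen
}

test_that("the Circle of Willis joins the carotid and vertebrobasilar routes", {
  ps <- artery_parameter_set("scenario1")
  seg <- ps$segments
  # the communicating-pathway property concerns the intracranial subgraph
  intracranial <- c("ica_2_l", "ica_2_r", "basilar", "pcoa_l", "pcoa_r",
                    "acoa", "aca_1_l", "aca_1_r", "pca_1_l", "pca_1_r")
  cerebral_nodes <- ps$terminals$artery_node[
    ps$terminals$reference == "icp_coupled"]
  # from the carotid root only (cut the vertebrals)
  carotid <- reachable_from(seg, c("cca_l_e", "cca_r_e"),
                            drop = c("vertebral_l", "vertebral_r"))
  expect_true(all(cerebral_nodes %in% carotid))
  # from the vertebrobasilar root only (cut the internal carotids)
  posterior <- reachable_from(seg, "bas_j",
                              drop = c("ica_1_l", "ica_1_r"))
  expect_true(all(cerebral_nodes %in% posterior))
  # removing the anterior communicating artery disconnects the two ACA
  # territories except through the posterior route
  cow <- seg[seg$name %in% intracranial, ]
  aca <- reachable_from(cow, "aca_j_l",
                        drop = c("acoa", "pcoa_l", "pcoa_r"))
  expect_false("aca_j_r" %in% aca)
  aca_post <- reachable_from(cow, "aca_j_l", drop = "acoa")
  expect_true("aca_j_r" %in% aca_post)
})

test_that("outlet flows balance the cardiac inflow over a settled cycle", {
  ps <- artery_parameter_set("scenario1")
  net <- build_network(40, ps)
  for (tn in ps$terminals$name) {
    net <- add_probe(net, paste0("q_", tn), "flow", paste0("R_d_", tn))
  }
  net <- add_probe(net, "q_in", "flow", "Q_heart")
  sys <- assemble(net)
  run <- integrate_circuit(sys, solver_config(), c(0, 12),
                           init = default_init(sys))
  sel <- run$probes$q_in$t >= 10 & run$probes$q_in$t < 10.8
  vol <- function(p) mean(p$v[sel]) * 0.8
  v_in <- vol(run$probes$q_in)
  v_out <- sum(vapply(ps$terminals$name, function(tn) {
    vol(run$probes[[paste0("q_", tn)]])
  }, 0))
  expect_lt(abs(v_out - v_in) / v_in, 0.01)
})
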