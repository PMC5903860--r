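# Constructs a 2-lipid-per-leaflet bilayer whose terminal carbons can be
# scripted frame by frame, for analytic velocity/protrusion checks.
scripted_terminal_traj <- function(z_ch3_upper, dxy = NULL, nf = length(z_ch3_upper)) {
  mb <- manual_bilayer(pz = 2, box = c(5, 5, 10), n_side = 2)
  term <- mb$topo$lipids$sn1_terminal[1] # an upper-leaflet chain
  frames <- lapply(seq_len(nf), function(i) {
    m <- mb$frame$coords
    m[term, 3] <- z_ch3_upper[i]
    if (!is.null(dxy)) m[term, 1:2] <- m[term, 1:2] + dxy[i, ]
    md_frame(m, mb$frame$box, time = (i - 1) * 10)
  })
  list(traj = md_trajectory(frames), topo = mb$topo, term = term)
}

test_that("velocity of constant-step motion equals the analytic value", {
  # +0.01 nm in z every 10 ps -> 1.0 nm/ns, averaged over 8 chains -> 0.125
  s <- scripted_terminal_traj(z_ch3_upper = 6 + 0.01 * (0:20))
  v <- terminal_velocity(s$traj, s$topo, step_ps = 10)
  v_sn1 <- v$velocity_z[v$chain_label == "sn1"]
  expect_equal(v_sn1, 1.0 / 8) # 7 of the 8 sn1 chains are stationary
  expect_equal(v$velocity_xy[v$chain_label == "sn1"], 0)
  expect_equal(v$velocity_z[v$chain_label == "sn2"], 0)

  # stationary everything: all velocities zero
  s0 <- scripted_terminal_traj(rep(6, 10))
  v0 <- terminal_velocity(s0$traj, s0$topo)
  expect_true(all(v0$velocity_z == 0 & v0$velocity_xy == 0))

  expect_error(terminal_velocity(s$traj, s$topo, step_ps = 5), "smaller")
  expect_error(terminal_velocity(s$traj, s$topo, step_ps = 15), "multiple")
})

test_that("velocities are invariant under translation and z rotation", {
  dxy <- cbind(cumsum(rep(0.02, 12)), cumsum(rep(-0.01, 12)))
  s <- scripted_terminal_traj(6 + 0.005 * (0:11), dxy = dxy)
  v0 <- terminal_velocity(s$traj, s$topo)

  shift <- c(0.5, -0.3, 0.9)
  traj_t <- s$traj
  for (f in seq_along(traj_t$times)) traj_t$coords[[f]] <-
    sweep(traj_t$coords[[f]], 2, shift, "+")
  vt <- terminal_velocity(traj_t, s$topo)
  expect_equal(vt$velocity_z, v0$velocity_z, tolerance = 1e-9)
  expect_equal(vt$velocity_xy, v0$velocity_xy, tolerance = 1e-9)

  th <- 0.7 # rotate about z through the box centre
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  traj_r <- s$traj
  for (f in seq_along(traj_r$times)) {
    c0 <- sweep(traj_r$coords[[f]], 2, c(2.5, 2.5, 0))
    traj_r$coords[[f]] <- sweep(c0 %*% rot, 2, c(2.5, 2.5, 0), "+")
  }
  vr <- terminal_velocity(traj_r, s$topo)
  expect_equal(vr$velocity_xy, v0$velocity_xy, tolerance = 1e-9)
  expect_equal(vr$velocity_z, v0$velocity_z, tolerance = 1e-9)
})

test_that("random-walk velocity recovers the planted mean within 3 SE", {
  cfg <- bilayer_config(n_lipids_per_leaflet = 16, waters_per_lipid = 1,
                        n_frames = 400, seed = 17,
                        sn1_motion = chain_motion("walk", step_sd = 0.02),
                        sn2_motion = chain_motion("walk", step_sd = 0.06))
  g <- make_bilayer_trajectory(cfg)
  v <- terminal_velocity(g$traj, g$topo, step_ps = 10)
  for (lab in c("sn1", "sn2")) {
    tr <- g$truth$chains[[lab]]
    got <- v$velocity_z[v$chain_label == lab]
    # realised value matches exactly (the generator scripts the steps)
    expect_equal(got, tr$realized_velocity_z, tolerance = 1e-9)
    # and the planted distributional mean within 3 standard errors
    expect_lt(abs(got - tr$expected_velocity_z), 3 * tr$se_velocity_z)
  }
  # dominance: sn2 motion parameters strictly exceed sn1's
  expect_gt(v$velocity_z[v$chain_label == "sn2"],
            v$velocity_z[v$chain_label == "sn1"])
})

test_that("torsion scoring: straight chains 0, planted hairpin 1, strict 100 deg", {
  mb <- manual_bilayer(pz = 2, n_side = 2, sn1_len = 7, sn2_len = 7)
  traj <- static_traj(mb$frame, nf = 2)
  tf <- torsion_frequency(traj, mb$topo)
  expect_true(all(tf$torsion_frequency == 0)) # all-trans chains: 180 degrees

  # plant a single 60 degree fold on one sn1 chain, vertex at carbon 4
  ids <- mb$topo$lipids$sn1_ids[[1]]
  m <- mb$frame$coords
  b <- 0.3
  p4 <- m[ids[4], ]
  w <- c(sin(pi / 3), 0, cos(pi / 3)) # 60 degrees to the upward return
  for (k in 5:7) m[ids[k], ] <- p4 + (k - 4) * b * w
  traj2 <- static_traj(md_frame(m, mb$frame$box), nf = 2)
  # brute-force oracle: recompute every interior angle directly
  angle_at <- function(mm, a, v, bb) {
    u1 <- mm[a, ] - mm[v, ]; u2 <- mm[bb, ] - mm[v, ]
    acos(sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))) * 180 / pi
  }
  n_below <- 0
  for (lip in seq_len(nrow(mb$topo$lipids))) {
    for (chain in c("sn1_ids", "sn2_ids")) {
      cid <- mb$topo$lipids[[chain]][[lip]]
      for (n in 3:(length(cid) - 2)) {
        if (angle_at(m, cid[n - 2], cid[n], cid[n + 2]) < 100) n_below <- n_below + 1
      }
    }
  }
  expect_equal(n_below, 1) # the planted fold is the only sub-threshold angle
  tf2 <- torsion_frequency(traj2, mb$topo)
  expect_equal(tf2$torsion_frequency[tf2$chain_label == "sn1"], 1 / 8)
  expect_equal(tf2$torsion_frequency[tf2$chain_label == "sn2"], 0)

  # boundary convention: exactly 100 degrees is NOT a torsion
  m3 <- mb$frame$coords
  w100 <- c(sin(pi * 100 / 180), 0, cos(pi * 100 / 180))
  for (k in 5:7) m3[ids[k], ] <- m3[ids[4], ] + (k - 4) * b * w100
  traj3 <- static_traj(md_frame(m3, mb$frame$box), nf = 1)
  tf3 <- torsion_frequency(traj3, mb$topo)
  expect_equal(tf3$torsion_frequency[tf3$chain_label == "sn1"], 0)
  # ... while 99.9 degrees is
  w999 <- c(sin(pi * 99.9 / 180), 0, cos(pi * 99.9 / 180))
  for (k in 5:7) m3[ids[k], ] <- m3[ids[4], ] + (k - 4) * b * w999
  tf4 <- torsion_frequency(static_traj(md_frame(m3, mb$frame$box), 1), mb$topo)
  expect_equal(tf4$torsion_frequency[tf4$chain_label == "sn1"], 1 / 8)
})

test_that("module torsions equal the brute-force oracle on random frames", {
  cfg <- bilayer_config(n_lipids_per_leaflet = 4, waters_per_lipid = 1,
                        sn1_length = 8, sn2_length = 10,
                        n_frames = 10, seed = 29,
                        sn2_motion = chain_motion("torsion", torsion_rate = 0.4))
  g <- make_bilayer_trajectory(cfg)
  tf <- torsion_frequency(g$traj, g$topo)
  # independent recomputation over every frame, chain and interior carbon
  oracle <- function(label) {
    col <- paste0(label, "_ids")
    tot <- 0
    for (f in seq_along(g$traj$times)) {
      m <- g$traj$coords[[f]]
      for (lip in seq_len(nrow(g$topo$lipids))) {
        cid <- g$topo$lipids[[col]][[lip]]
        for (n in 3:(length(cid) - 2)) {
          u1 <- m[cid[n - 2], ] - m[cid[n], ]
          u2 <- m[cid[n + 2], ] - m[cid[n], ]
          cosang <- min(1, max(-1, sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))))
          if (acos(cosang) * 180 / pi < 100) tot <- tot + 1
        }
      }
    }
    tot / length(g$traj$times) / nrow(g$topo$lipids)
  }
  expect_equal(tf$torsion_frequency[tf$chain_label == "sn1"], oracle("sn1"),
               tolerance = 1e-9)
  expect_equal(tf$torsion_frequency[tf$chain_label == "sn2"], oracle("sn2"),
               tolerance = 1e-9)
  # the generator's realised schedule agrees too
  expect_equal(tf$torsion_frequency[tf$chain_label == "sn2"],
               g$truth$chains$sn2$realized_torsion_frequency, tolerance = 1e-9)
})

test_that("protrusion events count square-wave rising edges with leaflet sign", {
  # upper-leaflet CH3 square wave crossing glycerol 4 times (2 up, 2 down)
  gl_z <- 6.8
  zs <- c(rep(6.0, 3), rep(7.1, 3), rep(6.0, 3), rep(7.1, 3), rep(6.0, 2))
  s <- scripted_terminal_traj(zs)
  pc <- protrusion_count(s$traj, s$topo)
  expect_equal(pc$n_events[pc$chain_label == "sn1"], 2)
  expect_equal(pc$n_events[pc$chain_label == "sn2"], 0)

  # always below glycerol (toward the core): no events
  s0 <- scripted_terminal_traj(rep(6.0, 10))
  pc0 <- protrusion_count(s0$traj, s0$topo)
  expect_true(all(pc0$n_events == 0))

  # lower leaflet: outward is -z; CH3 dropping below its glycerol counts
  mb <- manual_bilayer(pz = 2, box = c(5, 5, 10), n_side = 2)
  low <- which(mb$frame$coords[mb$topo$lipids$phosphate_id, 3] < 5)[1]
  term_low <- mb$topo$lipids$sn1_terminal[low]
  gl_low <- mb$topo$lipids$glycerol_id[low]
  frames <- lapply(1:4, function(i) {
    m <- mb$frame$coords
    m[term_low, 3] <- if (i %in% c(2, 3)) m[gl_low, 3] - 0.2 else m[gl_low, 3] + 0.5
    md_frame(m, mb$frame$box, time = (i - 1) * 10)
  })
  pc_low <- protrusion_count(md_trajectory(frames), mb$topo)
  expect_equal(pc_low$n_events[pc_low$chain_label == "sn1"], 1)
})

test_that("planted square waves are recovered and sn2 dominance holds", {
  cfg <- bilayer_config(n_lipids_per_leaflet = 8, waters_per_lipid = 1,
                        n_frames = 300, seed = 41,
                        sn1_motion = chain_motion("protrusion",
                                                  protrusion_period = 100,
                                                  protrusion_amplitude = 0.2),
                        sn2_motion = chain_motion("protrusion",
                                                  protrusion_period = 20,
                                                  protrusion_amplitude = 0.2))
  g <- make_bilayer_trajectory(cfg)
  pc <- protrusion_count(g$traj, g$topo)
  expect_equal(pc$n_events[pc$chain_label == "sn1"],
               g$truth$chains$sn1$planted_events_total)
  expect_equal(pc$n_events[pc$chain_label == "sn2"],
               g$truth$chains$sn2$planted_events_total)
  expect_gt(pc$n_events[pc$chain_label == "sn2"],
            pc$n_events[pc$chain_label == "sn1"])
})

test_that("sn2-dominant torsion schedules order the torsion metric", {
  cfg <- bilayer_config(n_lipids_per_leaflet = 8, waters_per_lipid = 1,
                        sn1_length = 8, sn2_length = 10,
                        n_frames = 120, seed = 43,
                        sn1_motion = chain_motion("torsion", torsion_rate = 0.05),
                        sn2_motion = chain_motion("torsion", torsion_rate = 0.5))
  g <- make_bilayer_trajectory(cfg)
  tf <- torsion_frequency(g$traj, g$topo)
  expect_gt(tf$torsion_frequency[tf$chain_label == "sn2"],
            tf$torsion_frequency[tf$chain_label == "sn1"])
})
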