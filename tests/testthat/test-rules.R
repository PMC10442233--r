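test_that("connections carry kind, jump and span as defined", {
  meander <- connections_of(parse_topology("1234:udud"))
  expect_equal(nrow(meander), 3)
  expect_true(all(meander$kind == "anti"))
  expect_equal(meander$jump, c(0, 0, 0))
  expect_true(all(meander$face == "none"))

  c1342 <- connections_of(parse_topology("1342:uddd"))
  expect_equal(c1342$kind, c("anti", "para", "para"))
  expect_equal(c1342$jump, c(2, 1, 0))
  expect_equal(c1342$p_start, c(1, 4, 2))
  expect_equal(c1342$p_end, c(4, 2, 3))

  c3142 <- connections_of(parse_topology("3142:uuuu"))
  expect_true(all(c3142$kind == "para"))
  expect_equal(c3142$jump, c(1, 2, 1))
})

test_that("connection faces follow the right-handed parity convention", {
  # antiparallel hairpins have no face
  expect_identical(connection_face(parse_topology("1234:udud"), 1), "none")
  # para, up strands: rightward vs leftward travel cross opposite faces
  right <- connection_face(parse_topology("123:uuu"), 1)   # 1 -> 2, rightward
  left <- connection_face(parse_topology("213:uuu"), 1)    # pos 2 -> 1, leftward
  expect_true(right %in% c("front", "back"))
  expect_false(right == left)
  # Rz flips every non-none face; Ry preserves them
  for (seed in 1:15) {
    t <- random_topology(sample(4:6, 1), seed + 300)
    f0 <- connections_of(t)$face
    frz <- connections_of(symmetry_images(t)$Rz)$face
    fry <- connections_of(symmetry_images(t)$Ry)$face
    nn <- f0 != "none"
    expect_identical(frz[!nn], f0[!nn])
    expect_true(all(frz[nn] != f0[nn]))
    expect_identical(fry, f0)
  }
})

test_that("ending sides exist for para connections only and flip under Rz", {
  t <- parse_topology("1342:uddd")
  expect_identical(ending_side(t, 1), "none")   # anti connection
  expect_true(ending_side(t, 2) %in% c("front", "back"))
  for (seed in 1:15) {
    t <- random_topology(sample(4:6, 1), seed + 400)
    co <- connections_of(t)
    erz <- connections_of(symmetry_images(t)$Rz)$ending_side
    para <- co$kind == "para"
    expect_true(all(erz[para] != co$ending_side[para]))
    expect_true(all(erz[!para] == "none"))
  }
})

test_that("para connections of equal jump parity arriving at adjacent parallel
           strands from the same travel direction share an ending side", {
  # 3124:uuuu: connections 1 (jump 0) and 3 (jump 2) both travel rightward
  # and end on adjacent parallel strands
  t <- parse_topology("3124:uuuu")
  co <- connections_of(t)
  expect_equal(co$jump[c(1, 3)], c(0, 2))
  expect_equal(abs(co$p_end[1] - co$p_end[3]), 1)
  expect_identical(co$ending_side[1], co$ending_side[3])
})

test_that("the Greek-key exemption matches the motif and its permutants", {
  expect_true(greek_key_exempt(parse_topology("4123:dudu"), 3))
  expect_true(greek_key_exempt(parse_topology("2341:udud"), 1))
  expect_true(greek_key_exempt(parse_topology("3412:udud"), 2))
  # non-alternating window: not exempt
  expect_false(greek_key_exempt(parse_topology("1342:uddd"), 1))
  # para jump-2 connections are never exempt
  expect_false(greek_key_exempt(parse_topology("3142:uuuu"), 2))
  # embedded Greek keys inside a larger sheet, at both window offsets
  t5 <- parse_topology("52341:dudud")
  expect_true(greek_key_exempt(t5, 1))  # window at positions 2..5
  expect_true(greek_key_exempt(t5, 4))  # window at positions 1..4
})

test_that("the three rules reproduce the worked verdicts", {
  # meander: clean
  m <- classify_topology(parse_topology("1234:udud"))
  expect_true(m$frustration_free)
  # 1342:uddd: jump violation on connection 1, an overlap violation,
  # and no ending violation
  f <- classify_topology(parse_topology("1342:uddd"))
  expect_false(f$frustration_free)
  expect_true(any(f$violations$rule == "jump_distance" &
                    f$violations$conn_i == 1))
  expect_true(any(f$violations$rule == "overlap"))
  expect_false(any(f$violations$rule == "ending"))
  # the all-parallel knot-forming 3142 order is frustration-free
  expect_true(classify_topology(parse_topology("3142:uuuu"))$frustration_free)
  # Greek key and circular permutants: free via the exemption
  for (s in c("4123:dudu", "2341:udud", "3412:udud"))
    expect_true(classify_topology(parse_topology(s))$frustration_free)
})

test_that("rule verdicts are invariant across all four symmetry images", {
  en <- enumerate_topologies(4)
  for (s in en$topology) {
    ref <- violation_set(classify_topology(parse_topology(s)))
    for (img in symmetry_images(parse_topology(s))[-1])
      expect_identical(violation_set(classify_topology(img)), ref)
  }
  for (n in 5:6) for (seed in 1:25) {
    t <- random_topology(n, seed + 500 + 37 * n)
    verdicts <- vapply(symmetry_images(t), function(x)
      classify_topology(x)$frustration_free, logical(1))
    expect_length(unique(verdicts), 1)
  }
})

test_that("a global face flip (Rx) changes no violation", {
  # Rx keeps positions and flips every face and ending side, so identical
  # violation sets here show the rules depend only on relative sides
  for (seed in 1:25) {
    t <- random_topology(sample(4:6, 1), seed + 600)
    expect_identical(
      violation_set(classify_topology(symmetry_images(t)$Rx)),
      violation_set(classify_topology(t)))
  }
})

test_that("S/D verdicts agree with the mock-coordinate connector faces", {
  # three-strand space exhaustively: same-face calls from routed mock
  # connectors equal the analytic ones used by the overlap rule
  for (s in enumerate_topologies(3)$topology) {
    t <- parse_topology(s)
    analytic <- connections_of(t)$face
    routed <- mock_coordinates(t)$connectors$face
    expect_identical(routed, analytic)
  }
})
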