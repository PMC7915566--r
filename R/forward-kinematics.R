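# Planar forward kinematics of the sagittal chain, shared by the synthetic
# generator, the whole-body CoM computation and the test oracles.
#
# Coordinate convention (fixed across the package): x anterior (+),
# y vertical up (+), z mediolateral; the sagittal motion lives in x-y.
#
# Joint-angle conventions (degrees):
#   pelvis  p : anterior pelvic tilt, positive when the anterior pelvis
#               markers sit lower than the posterior ones
#   hip     h : hip flexion relative to the pelvis line, 0 in neutral standing
#   knee    k : knee flexion, 0 = full extension
#   ankle   a : dorsiflexion positive, 0 in neutral standing (foot flat,
#               shank vertical)
#
# Derived absolute segment orientations:
#   phi_t = h - p   thigh lean from vertical (hip posterior of knee positive)
#   phi_s = k - phi_t  shank lean from vertical (knee anterior of ankle +)
#   phi_f = a - phi_s  foot pitch from flat (toes up positive)

#' Positions of the planar marker set for given joint angles
#'
#' @param angles data frame or list with numeric vectors `pelvis`, `hip`,
#'   `knee`, `ankle` in degrees (equal lengths)
#' @param root two-column matrix (or length-2 vector) of ankle-joint x,y
#'   positions in m
#' @param subject a [subject_spec()]
#' @return list of two-column (x, y) matrices: `ankle`, `knee`, `hip`,
#'   `pelvis_centroid`, `pelvis_ant`, `pelvis_post`, `heel`, `toe`
#' @keywords internal
fk_markers <- function(angles, root, subject) {
  p <- angles$pelvis * DEG2RAD
  h <- angles$hip * DEG2RAD
  k <- angles$knee * DEG2RAD
  a <- angles$ankle * DEG2RAD
  n <- length(p)
  if (is.null(dim(root))) root <- matrix(root, n, 2, byrow = TRUE)
  L <- subject$segment_lengths

  phi_t <- h - p
  phi_s <- k - phi_t
  phi_f <- a - phi_s

  A <- root
  K <- cbind(A[, 1] + L$shank * sin(phi_s), A[, 2] + L$shank * cos(phi_s))
  H <- cbind(K[, 1] - L$thigh * sin(phi_t), K[, 2] + L$thigh * cos(phi_t))
  C <- cbind(H[, 1] + L$pelvis_up * sin(p), H[, 2] + L$pelvis_up * cos(p))
  half_d <- L$pelvis_depth / 2
  ant  <- cbind(C[, 1] + half_d * cos(p), C[, 2] - half_d * sin(p))
  post <- cbind(C[, 1] - half_d * cos(p), C[, 2] + half_d * sin(p))

  h_a <- L$ankle_height
  x_heel <- -0.05
  x_toe <- 0.75 * L$foot
  heel <- cbind(A[, 1] + cos(phi_f) * x_heel + sin(phi_f) * h_a,
                A[, 2] + sin(phi_f) * x_heel - cos(phi_f) * h_a)
  toe  <- cbind(A[, 1] + cos(phi_f) * x_toe + sin(phi_f) * h_a,
                A[, 2] + sin(phi_f) * x_toe - cos(phi_f) * h_a)

  list(ankle = A, knee = K, hip = H, pelvis_centroid = C,
       pelvis_ant = ant, pelvis_post = post, heel = heel, toe = toe)
}

#' Whole-body centre of mass from planar marker positions
#'
#' Sums segment CoM positions (foot, shank, thigh from marker geometry;
#' head-arms-trunk above the pelvis centroid along the pelvis normal) with
#' anthropometric masses. Assumes bilateral symmetry (one leg's markers,
#' leg segments counted twice).
#'
#' @param mk list of (x, y) matrices as returned by [fk_markers()]
#' @param model a [build_body_model()] result
#' @return two-column matrix of whole-body CoM (x, y) in m
#' @keywords internal
whole_body_com <- function(mk, model) {
  subject <- model$subject
  seg <- function(s) model_segment(model, s)
  f <- seg("foot"); s <- seg("shank"); t <- seg("thigh")
  hat <- seg("head_arms_trunk")

  com_foot  <- mk$heel + f$com_fraction * (mk$toe - mk$heel)
  com_shank <- mk$knee + s$com_fraction * (mk$ankle - mk$knee)
  com_thigh <- mk$hip  + t$com_fraction * (mk$knee - mk$hip)

  # pelvis orientation recovered from the markers themselves
  dxy <- mk$pelvis_ant - mk$pelvis_post
  p <- -atan2(dxy[, 2], dxy[, 1])
  d_hat <- subject$segment_lengths$hat_up
  com_hat <- cbind(mk$pelvis_centroid[, 1] + d_hat * sin(p),
                   mk$pelvis_centroid[, 2] + d_hat * cos(p))

  total <- 2 * (f$mass + s$mass + t$mass) + hat$mass
  (2 * (f$mass * com_foot + s$mass * com_shank + t$mass * com_thigh) +
      hat$mass * com_hat) / total
}

# CoM (x, y) for a single pose given joint angles (deg) and ankle root.
com_at_pose <- function(pelvis, hip, knee, ankle, root, model) {
  mk <- fk_markers(list(pelvis = pelvis, hip = hip, knee = knee, ankle = ankle),
                   matrix(root, 1, 2), model$subject)
  whole_body_com(mk, model)[1, ]
}

# Pelvis-marker centroid y for a single pose.
pelvis_height_at_pose <- function(pelvis, hip, knee, ankle, root, subject) {
  mk <- fk_markers(list(pelvis = pelvis, hip = hip, knee = knee, ankle = ankle),
                   matrix(root, 1, 2), subject)
  mk$pelvis_centroid[1, 2]
}

# Numeric Jacobian (m per degree) of a scalar pose function wrt the four
# joint angles, at the given pose.
pose_jacobian <- function(fun, pose, step = 0.01) {
  vapply(seq_along(pose), function(j) {
    up <- pose; up[j] <- up[j] + step
    dn <- pose; dn[j] <- dn[j] - step
    (fun(up) - fun(dn)) / (2 * step)
  }, numeric(1))
}
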