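# Analytic and Monte-Carlo reference models for the measured statistics.

#' Physical constants for filament mechanics
#'
#' @param kappa flexural rigidity of F-actin, pN um^2.
#' @param filament_diameter nm.
#' @param rod_length representative branch length for the rigid-rod model, nm.
#' @export
physical_constants <- function(kappa = 0.040, filament_diameter = 8,
                               rod_length = 15.4) {
  stopifnot(kappa >= 0, filament_diameter > 0, rod_length > 0)
  list(kappa = kappa, filament_diameter = filament_diameter,
       rod_length = rod_length)
}

#' Random-orientation reference
#'
#' For filaments with uniformly random 3D orientations the angle alpha to
#' any fixed axis, folded to \[0, 90\] degrees, has density sin(alpha); the
#' mean is exactly 1 radian = 57.2958 degrees and the median 60 degrees.
#'
#' @return list `mean_deg`, `median_deg`, and `density`: a function of angle
#'   in degrees returning the probability density (per degree) on \[0, 90\].
#' @export
random_orientation_reference <- function() {
  list(mean_deg = 180 / pi,
       median_deg = 60,
       density = function(alpha_deg)
         ifelse(alpha_deg >= 0 & alpha_deg <= 90,
                sin(alpha_deg * pi / 180) * pi / 180, 0))
}

#' Uniform random unit vectors
#'
#' Sampled as normalized 3D Gaussian draws (exactly uniform on the sphere).
#'
#' @param n number of vectors.
#' @return n x 3 matrix of unit vectors.
#' @export
random_unit_vectors <- function(n) {
  v <- matrix(rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

#' Random-branching angle reference
#'
#' Draws `n` triples of independent uniform unit vectors, computes the three
#' pairwise angles per triple, and sorts them ascending. Completely random
#' branching at a rank-3 node gives sorted means of about 53.6, 95.3 and
#' 121.1 degrees with SDs of about 24.4, 27.1 and 30.9 degrees.
#'
#' @param n number of triples.
#' @param seed RNG seed.
#' @return list `means`, `sds` (each length 3, sorted ranks), and `angles`:
#'   an n x 3 matrix of the sorted triples.
#' @export
random_branching_angle_reference <- function(n = 1e5, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  u <- random_unit_vectors(n)
  v <- random_unit_vectors(n)
  w <- random_unit_vectors(n)
  ang <- function(a, b)
    acos(pmin(1, pmax(-1, rowSums(a * b)))) * 180 / pi
  A <- cbind(ang(u, v), ang(u, w), ang(v, w))
  A <- t(apply(A, 1, sort))
  list(means = colMeans(A),
       sds = apply(A, 2, sd),
       angles = A)
}

#' Rigid-rod orientation near a flat wall
#'
#' Branches are approximated as straight rigid rods of fixed length whose
#' centre sits at a given distance from a flat membrane; orientations are
#' uniform among those that do not cross the wall. At distances of at least
#' half the rod length the mean folded angle to the wall normal is the
#' unconstrained 57.2958 degrees; as the distance goes to 0 the rod must lie
#' parallel to the membrane and the mean goes to 90 degrees.
#'
#' @param rod_length nm.
#' @param distance_to_wall nm (centre of the rod).
#' @param n Monte-Carlo sample size (`method = "mc"`).
#' @param seed RNG seed (`method = "mc"`).
#' @param method `"analytic"` (closed form) or `"mc"` (rejection sampling).
#' @return mean angle in degrees.
#' @export
rigid_rod_orientation_model <- function(rod_length = 15.4,
                                        distance_to_wall = 10,
                                        n = 1e5, seed = 1L,
                                        method = c("analytic", "mc")) {
  stopifnot(rod_length > 0, distance_to_wall >= 0)
  method <- match.arg(method)
  h <- rod_length / 2
  if (method == "analytic") {
    # admissible folded angles alpha in [alpha0, 90], alpha0 = acos(d/h),
    # density sin(alpha); mean = (1 - sin a0 + a0 cos a0) / cos a0 radians
    if (distance_to_wall >= h) return(180 / pi)
    a0 <- acos(distance_to_wall / h)
    if (abs(cos(a0)) < 1e-12) return(90)
    mean_rad <- (1 - sin(a0) + a0 * cos(a0)) / cos(a0)
    return(mean_rad * 180 / pi)
  }
  set.seed(seed)
  angs <- numeric(0)
  while (length(angs) < n) {
    v <- random_unit_vectors(n)
    # wall normal = z; rod crosses the wall iff h*|vz| > d
    ok <- h * abs(v[, 3]) <= distance_to_wall
    a <- acos(abs(v[ok, 3])) * 180 / pi
    angs <- c(angs, a)
  }
  mean(angs[seq_len(n)])
}

#' Euler buckling force of a filament
#'
#' `F = pi^2 * kappa / L^2`: the minimal compressive force needed to buckle
#' a filament of length L and flexural rigidity kappa. With
#' kappa = 0.040 pN um^2 a 1 um filament buckles at about 0.4 pN.
#'
#' @param kappa flexural rigidity, pN um^2.
#' @param length filament length, um.
#' @return force in pN.
#' @export
buckling_force <- function(kappa = 0.040, length = 1) {
  stopifnot(kappa >= 0, length > 0)
  pi^2 * kappa / length^2
}

#' Base angle of the isosceles-triangle picture of tortuosity
#'
#' A branch of tortuosity t is represented as an isosceles triangle whose
#' base is the Euclidean span and whose two equal sides sum to the arc
#' length; the base angle is `acos(1/t)`. A tortuosity of 1.15 corresponds
#' to 30 degrees.
#'
#' @param t tortuosity, >= 1.
#' @return angle in degrees.
#' @export
tortuosity_base_angle <- function(t) {
  if (any(t < 1)) stop("tortuosity must be >= 1")
  acos(1 / t) * 180 / pi
}

#' Random branch-end reference in a membrane shell
#'
#' Places `n_points` uniform random points in the given shell voxel set
#' (jittered within voxels), computes nearest-neighbour distances, and
#' repeats `n_reps` times. The reference distribution for the branch-end
#' clustering test.
#'
#' @param shell_voxels linear indices of shell voxels.
#' @param dims grid dimensions.
#' @param pitch voxel pitch, nm.
#' @param origin grid origin, nm.
#' @param n_points points per replicate (>= 2).
#' @param n_reps replicates.
#' @param seed RNG seed.
#' @return list `nn` (pooled NN distances), `mean`, `sd`.
#' @export
random_branch_end_reference <- function(shell_voxels, dims, pitch,
                                        origin = c(0, 0, 0),
                                        n_points, n_reps = 100L, seed = 1L) {
  if (length(shell_voxels) == 0) stop("empty shell")
  if (n_points < 2) stop("need at least 2 points")
  set.seed(seed)
  centers <- voxel_centers(arrayInd(shell_voxels, dims), pitch, origin)
  nn <- numeric(0)
  for (r in seq_len(n_reps)) {
    pick <- sample.int(nrow(centers), n_points, replace = TRUE)
    pts <- centers[pick, , drop = FALSE] +
      matrix(runif(3 * n_points, -pitch / 2, pitch / 2), n_points, 3)
    nn <- c(nn, nn_distances(pts))
  }
  list(nn = nn, mean = mean(nn), sd = sd(nn))
}
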