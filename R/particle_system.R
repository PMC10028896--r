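#' Construct a toy particle system
#'
#' A self-contained, non-periodic collection of point particles with
#' per-particle nonbonded parameters and optional valence terms. This is the
#' basic container every fixture generator returns and every energy routine
#' consumes. Units: nm, kcal/mol, K, elementary charge, amu.
#'
#' Valence terms are supplied as data frames with fixed columns
#' (1-based particle indices):
#' * `bonds`: `i, j, k_spring` (kcal/mol/nm²), `r0` (nm)
#' * `angles`: `i, j, k, k_angle` (kcal/mol/rad²), `theta0` (rad)
#' * `torsions`: `i, j, k, l, barrier` (kcal/mol), `periodicity`, `phase` (rad)
#' * `restraints`: `i, k_spring` (kcal/mol/nm²), `x0, y0, z0` (nm) — isotropic
#'   harmonic anchors to fixed points, also used for positional restraints
#' * `doublewells`: `i, axis` (1 = x, 2 = y, 3 = z), `barrier` (kcal/mol),
#'   `s0` (nm), `center` (nm), `tilt` (kcal/mol) — a quartic double well
#'   `barrier * ((s/s0)^2 - 1)^2 + tilt * (s/s0)` on one coordinate
#'   `s = x[i, axis] - center`, used to plant slow degrees of freedom
#'
#' @param positions n×3 numeric matrix of positions (nm).
#' @param charges Numeric vector, elementary charge.
#' @param lj_sigma Numeric vector, nm; strictly positive.
#' @param lj_epsilon Numeric vector, kcal/mol; non-negative.
#' @param masses Numeric vector, amu; strictly positive.
#' @param bonds,angles,torsions,restraints,doublewells Valence term tables
#'   (see Details); `NULL` means none.
#' @param tags Character vector of per-particle labels (`""` for untagged);
#'   recognised labels include `"mutating"`, `"counter"`, `"heavy"`,
#'   `"slow_dof"`.
#' @return An object of class `particle_system`.
#' @export
#' @examples
#' sys <- particle_system(
#'   positions = matrix(c(0, 0, 0, 0.3, 0, 0), 2, 3, byrow = TRUE),
#'   charges = c(1, -1), lj_sigma = c(0.3, 0.3), lj_epsilon = c(0.1, 0.1),
#'   masses = c(12, 12)
#' )
#' system_energy(sys, sys$positions)
particle_system <- function(positions, charges, lj_sigma, lj_epsilon, masses,
                            bonds = NULL, angles = NULL, torsions = NULL,
                            restraints = NULL, doublewells = NULL,
                            tags = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an n x 3 matrix")
  n <- nrow(positions)
  charges <- as.numeric(charges)
  lj_sigma <- as.numeric(lj_sigma)
  lj_epsilon <- as.numeric(lj_epsilon)
  masses <- as.numeric(masses)
  if (is.null(tags)) tags <- rep("", n)
  tags <- as.character(tags)
  lens <- c(length(charges), length(lj_sigma), length(lj_epsilon),
            length(masses), length(tags))
  if (any(lens != n)) stop("all per-particle arrays must have length n_particles")
  if (any(lj_sigma <= 0)) stop("lj_sigma must be positive")
  if (any(lj_epsilon < 0)) stop("lj_epsilon must be non-negative")
  if (any(masses <= 0)) stop("masses must be positive")

  bonds <- validate_terms(bonds, c("i", "j", "k_spring", "r0"), n, 2)
  angles <- validate_terms(angles, c("i", "j", "k", "k_angle", "theta0"), n, 3)
  torsions <- validate_terms(
    torsions, c("i", "j", "k", "l", "barrier", "periodicity", "phase"), n, 4)
  restraints <- validate_terms(
    restraints, c("i", "k_spring", "x0", "y0", "z0"), n, 1)
  doublewells <- validate_terms(
    doublewells, c("i", "axis", "barrier", "s0", "center", "tilt"), n, 1)
  if (!is.null(bonds) && any(bonds$k_spring < 0)) stop("k_spring must be >= 0")
  if (!is.null(restraints) && any(restraints$k_spring < 0))
    stop("restraint k_spring must be >= 0")

  structure(list(
    n_particles = n, positions = unname(positions), charges = charges,
    lj_sigma = lj_sigma, lj_epsilon = lj_epsilon, masses = masses,
    bonds = bonds, angles = angles, torsions = torsions,
    restraints = restraints, doublewells = doublewells, tags = tags
  ), class = "particle_system")
}

# shared validator: right columns, indices in range and distinct per term
validate_terms <- function(df, cols, n, n_idx) {
  if (is.null(df) || (is.data.frame(df) && nrow(df) == 0)) return(NULL)
  df <- as.data.frame(df)
  if (!all(cols %in% names(df))) {
    stop(sprintf("term table must have columns: %s", paste(cols, collapse = ", ")))
  }
  df <- df[cols]
  idx <- as.matrix(df[, seq_len(n_idx), drop = FALSE])
  if (any(idx < 1 | idx > n) || any(idx != round(idx))) {
    stop("term indices out of range")
  }
  if (n_idx > 1 && any(apply(idx, 1, function(r) anyDuplicated(r) > 0))) {
    stop("term indices must reference distinct particles")
  }
  df
}

#' @export
print.particle_system <- function(x, ...) {
  cat(sprintf("<particle_system> %d particles", x$n_particles))
  nt <- function(d) if (is.null(d)) 0L else nrow(d)
  cat(sprintf(
    " | bonds %d, angles %d, torsions %d, restraints %d, double wells %d\n",
    nt(x$bonds), nt(x$angles), nt(x$torsions), nt(x$restraints),
    nt(x$doublewells)))
  tg <- unique(x$tags[x$tags != ""])
  if (length(tg)) cat("  tags:", paste(tg, collapse = ", "), "\n")
  invisible(x)
}

## ---- plain (non-alchemical) reference energy, pure R ----

vec_norm <- function(v) sqrt(sum(v * v))

# interior angle at j for points a-b-c
angle_between <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / (vec_norm(u) * vec_norm(v))
  acos(max(-1, min(1, cosang)))
}

# dihedral angle for points a-b-c-d, in (-pi, pi]; NA for degenerate geometry
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (vec_norm(n1) < 1e-12 || vec_norm(n2) < 1e-12) return(NA_real_)
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  nb2 <- vec_norm(b2)
  atan2(sum(m1 * n2) / nb2, sum(n1 * n2))
}

#' Potential energy of a plain particle system
#'
#' Direct evaluation of the unmodified (non-alchemical) potential: screened
#' Coulomb and Lennard-Jones over all particle pairs (Lorentz-Berthelot
#' combination), plus all valence terms. Serves as the reference energy for
#' the hybrid endstate-equivalence property and for oracles; it is written in
#' plain R, independent of the compiled alchemical path.
#'
#' @param system A [particle_system()].
#' @param x n×3 configuration matrix (defaults to the stored positions).
#' @param screening_alpha Coulomb screening parameter (1/nm); 0 gives plain
#'   Coulomb.
#' @param coulomb_constant Coulomb constant, kcal·nm/(mol·e²).
#' @return Energy in kcal/mol.
#' @export
system_energy <- function(system, x = system$positions,
                          screening_alpha = 0,
                          coulomb_constant = alchrex_constants$coulomb) {
  stopifnot(inherits(system, "particle_system"))
  x <- as.matrix(x)
  n <- system$n_particles
  stopifnot(nrow(x) == n, ncol(x) == 3)
  e <- 0
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        r <- vec_norm(x[i, ] - x[j, ])
        qq <- system$charges[i] * system$charges[j]
        if (qq != 0) {
          ec <- coulomb_constant * qq / r
          if (screening_alpha > 0) ec <- ec * erfc_r(screening_alpha * r)
          e <- e + ec
        }
        eps <- sqrt(system$lj_epsilon[i] * system$lj_epsilon[j])
        if (eps > 0) {
          sig <- (system$lj_sigma[i] + system$lj_sigma[j]) / 2
          x6 <- (sig / r)^6
          e <- e + 4 * eps * x6 * (x6 - 1)
        }
      }
    }
  }
  e + valence_terms_energy(system, x)
}

erfc_r <- function(z) 2 * stats::pnorm(z * sqrt(2), lower.tail = FALSE)

# valence-only energy of a plain system (R reference path)
valence_terms_energy <- function(system, x) {
  e <- 0
  b <- system$bonds
  if (!is.null(b)) {
    for (t in seq_len(nrow(b))) {
      r <- vec_norm(x[b$i[t], ] - x[b$j[t], ])
      e <- e + 0.5 * b$k_spring[t] * (r - b$r0[t])^2
    }
  }
  a <- system$angles
  if (!is.null(a)) {
    for (t in seq_len(nrow(a))) {
      th <- angle_between(x[a$i[t], ], x[a$j[t], ], x[a$k[t], ])
      e <- e + 0.5 * a$k_angle[t] * (th - a$theta0[t])^2
    }
  }
  d <- system$torsions
  if (!is.null(d)) {
    for (t in seq_len(nrow(d))) {
      phi <- dihedral_angle(x[d$i[t], ], x[d$j[t], ], x[d$k[t], ], x[d$l[t], ])
      if (!is.na(phi)) {
        e <- e + d$barrier[t] * (1 + cos(d$periodicity[t] * phi - d$phase[t]))
      }
    }
  }
  rs <- system$restraints
  if (!is.null(rs)) {
    for (t in seq_len(nrow(rs))) {
      dvec <- x[rs$i[t], ] - c(rs$x0[t], rs$y0[t], rs$z0[t])
      e <- e + 0.5 * rs$k_spring[t] * sum(dvec * dvec)
    }
  }
  w <- system$doublewells
  if (!is.null(w)) {
    for (t in seq_len(nrow(w))) {
      s <- (x[w$i[t], w$axis[t]] - w$center[t]) / w$s0[t]
      e <- e + w$barrier[t] * (s^2 - 1)^2 + w$tilt[t] * s
    }
  }
  e
}

#' Export a configuration in XYZ format
#'
#' Writes a minimal XYZ file (coordinates in nm) for visual inspection of a
#' fixture. Untagged particles are written as element `C`; tagged particles
#' use the first letter of their tag, capitalised.
#'
#' @param system A [particle_system()].
#' @param path Output file path.
#' @param x Optional configuration (defaults to stored positions).
#' @param comment Comment line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(system, path, x = system$positions,
                      comment = "alchrex toy system (nm)") {
  x <- as.matrix(x)
  el <- ifelse(system$tags == "", "C", toupper(substr(system$tags, 1, 1)))
  lines <- c(
    as.character(nrow(x)), comment,
    sprintf("%s %.9f %.9f %.9f", el, x[, 1], x[, 2], x[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}
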