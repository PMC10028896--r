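## Hybrid topology: one system containing both endstates.
## Hybrid atom order: mapped atoms (ascending old index), then unmapped old
## atoms, then unmapped new atoms.

#' Classify hybrid atoms into alchemical atom classes
#'
#' Partitions the hybrid atom index range into the four classes used by the
#' alchemical potential: `unique_old` (unmapped, old side only), `unique_new`
#' (unmapped, new side only), `core` (mapped atoms whose interactions change
#' between endstates) and `environment` (mapped, unmodified). A mapped atom
#' is core if it is tagged `"mutating"`, if any of its nonbonded parameters
#' differ between endstates, or if it participates in a valence term whose
#' parameters differ.
#'
#' @param pair A [mutation_pair()].
#' @return List with integer index vectors `unique_old`, `unique_new`,
#'   `core`, `environment` (hybrid indices), the hybrid size `n_atoms`, and
#'   the index maps `old_to_hybrid`, `new_to_hybrid`.
#' @export
classify_atoms <- function(pair) {
  stopifnot(inherits(pair, "mutation_pair"))
  old <- pair$old_system; new <- pair$new_system
  map <- pair$atom_map
  if (nrow(map) > 0) map <- map[order(map[, 1]), , drop = FALSE]
  mapped_old <- map[, 1]; mapped_new <- map[, 2]
  un_old <- setdiff(seq_len(old$n_particles), mapped_old)
  un_new <- setdiff(seq_len(new$n_particles), mapped_new)
  n_map <- nrow(map)
  n_atoms <- n_map + length(un_old) + length(un_new)

  old_to_hybrid <- integer(old$n_particles)
  old_to_hybrid[mapped_old] <- seq_len(n_map)
  old_to_hybrid[un_old] <- n_map + seq_along(un_old)
  new_to_hybrid <- integer(new$n_particles)
  new_to_hybrid[mapped_new] <- seq_len(n_map)
  new_to_hybrid[un_new] <- n_map + length(un_old) + seq_along(un_new)

  core_flag <- logical(n_map)
  if (n_map > 0) {
    core_flag <- old$tags[mapped_old] == "mutating" |
      abs(old$charges[mapped_old] - new$charges[mapped_new]) > 0 |
      abs(old$lj_sigma[mapped_old] - new$lj_sigma[mapped_new]) > 0 |
      abs(old$lj_epsilon[mapped_old] - new$lj_epsilon[mapped_new]) > 0
    # valence terms whose parameters differ promote their mapped atoms to core
    vmatch <- match_valence(pair, old_to_hybrid, new_to_hybrid, n_map)
    for (tab in vmatch) {
      if (is.null(tab) || nrow(tab) == 0) next
      changed <- tab$mode == 0L & tab$differs
      if (any(changed)) {
        idx <- unlist(tab[changed, grepl("^at", names(tab)), drop = FALSE])
        idx <- idx[!is.na(idx) & idx <= n_map]
        core_flag[idx] <- TRUE
      }
    }
  }
  list(
    unique_old = if (length(un_old)) n_map + seq_along(un_old) else integer(0),
    unique_new = if (length(un_new)) n_map + length(un_old) + seq_along(un_new)
                 else integer(0),
    core = which(core_flag),
    environment = which(!core_flag),
    n_atoms = n_atoms,
    old_to_hybrid = old_to_hybrid,
    new_to_hybrid = new_to_hybrid
  )
}

# Match valence terms across endstates in hybrid indexing.
# Returns one table per term type with hybrid atom columns at1..at4, old/new
# parameter columns, a `mode` column and a `differs` flag.
# mode: 0 interpolate, 1 old-only scaled by (1-lambda), 2 new-only scaled by
# lambda, 3 static old (involves unique old atoms), 4 static new.
match_valence <- function(pair, old_to_hybrid, new_to_hybrid, n_map) {
  old <- pair$old_system; new <- pair$new_system

  remap <- function(df, idx_cols, to_hybrid) {
    if (is.null(df)) return(NULL)
    out <- df
    for (cc in idx_cols) out[[cc]] <- to_hybrid[df[[cc]]]
    out
  }
  build <- function(df_old, df_new, idx_cols, par_cols, canon) {
    df_old <- remap(df_old, idx_cols, old_to_hybrid)
    df_new <- remap(df_new, idx_cols, new_to_hybrid)
    n_idx <- length(idx_cols)
    rows <- list()
    key <- function(df, r) canon(unlist(df[r, idx_cols]))
    used_new <- if (is.null(df_new)) logical(0) else logical(nrow(df_new))
    keys_new <- if (is.null(df_new)) character(0) else
      vapply(seq_len(nrow(df_new)), function(r) key(df_new, r), "")
    mk_row <- function(at, p_old, p_new, mode, differs) {
      at <- c(at, rep(NA_integer_, 4 - length(at)))
      c(list(at1 = at[1], at2 = at[2], at3 = at[3], at4 = at[4]),
        setNames(as.list(p_old), paste0(par_cols, "_old")),
        setNames(as.list(p_new), paste0(par_cols, "_new")),
        list(mode = mode, differs = differs))
    }
    if (!is.null(df_old)) {
      for (r in seq_len(nrow(df_old))) {
        at <- unlist(df_old[r, idx_cols])
        p_old <- unlist(df_old[r, par_cols])
        if (any(at > n_map)) {  # involves unique old atoms: static, dummy rule
          rows[[length(rows) + 1]] <- mk_row(at, p_old, p_old, 3L, FALSE)
          next
        }
        hit <- which(!used_new & keys_new == key(df_old, r))
        if (length(hit)) {
          hit <- hit[1]; used_new[hit] <- TRUE
          p_new <- unlist(df_new[hit, par_cols])
          rows[[length(rows) + 1]] <-
            mk_row(at, p_old, p_new, 0L, any(p_old != p_new))
        } else {
          rows[[length(rows) + 1]] <- mk_row(at, p_old, p_old, 1L, TRUE)
        }
      }
    }
    if (!is.null(df_new)) {
      for (r in seq_len(nrow(df_new))) {
        if (used_new[r]) next
        at <- unlist(df_new[r, idx_cols])
        p_new <- unlist(df_new[r, par_cols])
        if (any(at > n_map)) {
          rows[[length(rows) + 1]] <- mk_row(at, p_new, p_new, 4L, FALSE)
        } else {
          rows[[length(rows) + 1]] <- mk_row(at, p_new, p_new, 2L, TRUE)
        }
      }
    }
    if (!length(rows)) return(NULL)
    do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  }

  canon_pair <- function(at) paste(sort(at), collapse = "-")
  canon_angle <- function(at) paste(at[2], paste(sort(at[c(1, 3)]), collapse = "-"))
  canon_torsion <- function(at) {
    fwd <- paste(at, collapse = "-"); rev <- paste(rev(at), collapse = "-")
    min(fwd, rev)
  }
  canon_single <- function(at) as.character(at[1])
  canon_dw <- function(at) paste(at, collapse = "-")  # (i, axis)

  list(
    bonds = build(old$bonds, new$bonds, c("i", "j"),
                  c("k_spring", "r0"), canon_pair),
    angles = build(old$angles, new$angles, c("i", "j", "k"),
                   c("k_angle", "theta0"), canon_angle),
    torsions = build(old$torsions, new$torsions, c("i", "j", "k", "l"),
                     c("barrier", "periodicity", "phase"), canon_torsion),
    restraints = build(old$restraints, new$restraints, "i",
                       c("k_spring", "x0", "y0", "z0"), canon_single),
    doublewells = build(
      # axis participates in matching, not interpolation
      if (is.null(old$doublewells)) NULL else old$doublewells,
      if (is.null(new$doublewells)) NULL else new$doublewells,
      "i", c("axis", "barrier", "s0", "center", "tilt"), canon_single)
  )
}

#' Build the hybrid system for a mutation
#'
#' Constructs the union topology containing both endstates: shared
#' coordinates for mapped atoms, per-atom old/new nonbonded parameters
#' (zero-interaction semantics for the absent side of unique atoms), merged
#' valence terms (dummy atoms retain their valence terms at all lambda;
#' matched terms with differing parameters interpolate linearly), and
#' nonbonded exclusions between unique-old and unique-new atoms, which never
#' coexist physically.
#'
#' @param pair A [mutation_pair()].
#' @return An object of class `hybrid_system`.
#' @export
#' @examples
#' hs <- build_hybrid(make_harmonic_ladder(1, 100, 200, seed = 1))
#' hs$atom_classes$core
build_hybrid <- function(pair) {
  cls <- classify_atoms(pair)
  old <- pair$old_system; new <- pair$new_system
  n <- cls$n_atoms
  map <- pair$atom_map
  if (nrow(map) > 0) map <- map[order(map[, 1]), , drop = FALSE]
  n_map <- nrow(map)

  inv_old <- integer(n); inv_old[cls$old_to_hybrid] <- seq_len(old$n_particles)
  inv_new <- integer(n); inv_new[cls$new_to_hybrid] <- seq_len(new$n_particles)

  is_uold <- seq_len(n) %in% cls$unique_old
  is_unew <- seq_len(n) %in% cls$unique_new
  has_old <- !is_unew
  has_new <- !is_uold

  masses <- numeric(n)
  masses[has_old] <- old$masses[inv_old[has_old]]
  m_new_side <- new$masses[inv_new[has_new]]
  if (n_map > 0) {
    m_old_mapped <- old$masses[map[, 1]]
    m_new_mapped <- new$masses[map[, 2]]
    if (any(abs(m_old_mapped - m_new_mapped) > 1e-9)) {
      stop("mapped atoms must have identical masses in both endstates")
    }
  }
  masses[is_unew] <- new$masses[inv_new[is_unew]]

  pick <- function(v_old, v_new, default = 0) {
    out <- rep(default, n)
    out[has_old] <- v_old[inv_old[has_old]]
    res_new <- rep(default, n)
    res_new[has_new] <- v_new[inv_new[has_new]]
    list(old = ifelse(has_old, out, default), new = ifelse(has_new, res_new, default))
  }
  q <- pick(old$charges, new$charges, 0)
  sg <- pick(old$lj_sigma, new$lj_sigma, 0.3)  # sigma placeholder where absent
  ep <- pick(old$lj_epsilon, new$lj_epsilon, 0)
  # absent side keeps its present-side sigma so combination rules stay sane
  sg$new[is_uold] <- sg$old[is_uold]
  sg$old[is_unew] <- sg$new[is_unew]

  positions <- matrix(0, n, 3)
  positions[has_old, ] <- old$positions[inv_old[has_old], , drop = FALSE]
  positions[is_unew, ] <- new$positions[inv_new[is_unew], , drop = FALSE]

  tags <- character(n)
  tags[has_old] <- old$tags[inv_old[has_old]]
  tags[is_unew] <- new$tags[inv_new[is_unew]]

  class_code <- integer(n)  # 0 env, 1 core, 2 unique_old, 3 unique_new
  class_code[cls$core] <- 1L
  class_code[cls$unique_old] <- 2L
  class_code[cls$unique_new] <- 3L

  excl <- if (length(cls$unique_old) && length(cls$unique_new)) {
    as.matrix(expand.grid(i = cls$unique_old, j = cls$unique_new))
  } else matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))

  valence <- match_valence(pair, cls$old_to_hybrid, cls$new_to_hybrid, n_map)
  # rest-exempt flag per restraint row (set by add_positional_restraints)
  if (!is.null(valence$restraints)) valence$restraints$rest_exempt <- FALSE

  obs <- pair$observables
  if (!is.null(obs)) {
    for (cc in c("i", "j", "k", "l")) {
      ok <- !is.na(obs[[cc]])
      obs[[cc]][ok] <- cls$old_to_hybrid[obs[[cc]][ok]]
    }
  }

  hs <- structure(list(
    n_atoms = n, positions = positions, masses = masses, tags = tags,
    q_old = q$old, q_new = q$new,
    sigma_old = sg$old, sigma_new = sg$new,
    eps_old = ep$old, eps_new = ep$new,
    atom_classes = cls[c("unique_old", "unique_new", "core", "environment")],
    class_code = class_code,
    valence = valence,
    excluded_pairs = excl,
    rest_membership = class_code != 0L,  # alchemical atoms; see assign_rest_region
    rest_radius = NA_real_,
    observables = obs,
    kind = pair$kind, temperature = pair$temperature,
    net_charge_change = pair$net_charge_change,
    analytic_delta_g = pair$analytic_delta_g,
    analytic_valid = pair$analytic_valid
  ), class = "hybrid_system")
  hs
}

#' @export
print.hybrid_system <- function(x, ...) {
  ac <- x$atom_classes
  cat(sprintf(
    "<hybrid_system> %d atoms | core %d, env %d, unique_old %d, unique_new %d\n",
    x$n_atoms, length(ac$core), length(ac$environment),
    length(ac$unique_old), length(ac$unique_new)))
  cat(sprintf("  REST members: %d (radius %s)\n", sum(x$rest_membership),
              ifelse(is.na(x$rest_radius), "alchemical atoms only",
                     paste0(x$rest_radius, " nm"))))
  invisible(x)
}

#' Assign the REST region of a hybrid system
#'
#' Marks as REST members all alchemical atoms (unique old, unique new, core)
#' plus every atom within `radius` of an alchemical atom in the reference
#' configuration. Membership is computed once from the reference
#' configuration and not updated during sampling. Interactions are then
#' classed `rest` (all atoms members), `inter` (some members) or `nonrest`
#' (none) when energies are evaluated.
#'
#' @param hybrid A `hybrid_system`.
#' @param reference_positions Configuration used to measure distances
#'   (defaults to the stored positions).
#' @param radius REST radius in nm (default 0.5).
#' @return The updated `hybrid_system`.
#' @export
assign_rest_region <- function(hybrid, reference_positions = hybrid$positions,
                               radius = 0.5) {
  stopifnot(inherits(hybrid, "hybrid_system"), radius >= 0)
  x <- as.matrix(reference_positions)
  alch <- which(hybrid$class_code != 0L)
  member <- hybrid$class_code != 0L
  if (length(alch) && is.finite(radius) && radius > 0) {
    for (i in seq_len(hybrid$n_atoms)) {
      if (member[i]) next
      d2 <- colSums((t(x[alch, , drop = FALSE]) - x[i, ])^2)
      if (any(d2 <= radius^2)) member[i] <- TRUE
    }
  } else if (is.infinite(radius)) {
    member[] <- TRUE
  }
  hybrid$rest_membership <- member
  hybrid$rest_radius <- radius
  hybrid
}

#' Add positional restraints to a hybrid system
#'
#' Adds an isotropic harmonic restraint anchoring each selected particle to
#' its current reference position, as used when diagnosing whether slow
#' convergence is caused by conformational sampling. The restraint energy is
#' non-alchemical (lambda-independent) and always classed non-REST so it is
#' never tempered.
#'
#' @param hybrid A `hybrid_system`.
#' @param selection Particles to restrain: a tag (e.g. `"heavy"`), the string
#'   `"all"`, or an integer vector of hybrid indices.
#' @param force_constant Spring constant in kcal/mol/Å² (the conventional
#'   reporting unit; converted internally to nm).
#' @return The updated `hybrid_system`.
#' @export
add_positional_restraints <- function(hybrid, selection = "all",
                                      force_constant = 50) {
  stopifnot(inherits(hybrid, "hybrid_system"), force_constant >= 0)
  idx <- if (is.numeric(selection)) {
    as.integer(selection)
  } else if (identical(selection, "all")) {
    seq_len(hybrid$n_atoms)
  } else {
    which(hybrid$tags %in% selection)
  }
  if (!length(idx)) {
    warning("empty restraint selection; system unchanged")
    return(hybrid)
  }
  k_nm <- force_constant * 100  # kcal/mol/A^2 -> kcal/mol/nm^2
  add <- data.frame(
    at1 = idx, at2 = NA_integer_, at3 = NA_integer_, at4 = NA_integer_,
    k_spring_old = k_nm, x0_old = hybrid$positions[idx, 1],
    y0_old = hybrid$positions[idx, 2], z0_old = hybrid$positions[idx, 3],
    k_spring_new = k_nm, x0_new = hybrid$positions[idx, 1],
    y0_new = hybrid$positions[idx, 2], z0_new = hybrid$positions[idx, 3],
    mode = 0L, differs = FALSE, rest_exempt = TRUE
  )
  old_r <- hybrid$valence$restraints
  hybrid$valence$restraints <- if (is.null(old_r)) add else {
    rbind(old_r[names(add)], add)
  }
  hybrid
}
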