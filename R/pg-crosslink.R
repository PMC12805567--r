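#' Cross-linking parameters
#'
#' @param P_cl probability that a selected pair forms a peptide cross-link.
#' @param P_l probability that a unit's direction is overridden to link
#'   between layers, with `l_direction` "up" or "down".
#' @param P_o probability that a third unit may join an existing dimer
#'   (oligomer extension).
#' @param reach maximum stem-tip separation for a sterically valid link, nm.
#' @return a `crosslink_params` list.
#' @export
crosslink_params <- function(P_cl = 0.5, P_l = 0, l_direction = c("up", "down"),
                             P_o = 0) {
  l_direction <- match.arg(l_direction)
  for (p in c(P_cl, P_l, P_o))
    if (p < 0 || p > 1) abort("cross-link probabilities must lie in [0, 1]")
  structure(list(P_cl = P_cl, P_l = P_l, l_direction = l_direction, P_o = P_o),
            class = "crosslink_params")
}

#' Form peptide cross-links between murein units
#'
#' Each unit carries a random left/right direction (assigned here, seeded).
#' Units are visited in random order; for unit U1 a partner U2 is taken on
#' the adjacent strand line in U1's direction (overridden with probability
#' `P_l` to the adjacent layer, forming an interlayer link). The pair links
#' with probability `P_cl`; whether or not a link forms, the pair is flagged
#' so it is never selected again. A unit joining an already-linked partner
#' (extending a dimer to an oligomer) is allowed with probability `P_o`.
#' Pairs beyond the geometric `reach` of the peptide stems are rejected as
#' sterically invalid.
#'
#' @param mesh a `pg_mesh`.
#' @param params a [crosslink_params()].
#' @param seed RNG seed.
#' @param reach maximum stem-tip separation, nm (default 2.2).
#' @return the mesh with `crosslinks` and `flagged` filled and unit
#'   directions assigned.
#' @export
crosslink_mesh <- function(mesh, params = crosslink_params(), seed = 1,
                           reach = 2.2) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  u <- mesh$units
  n <- nrow(u)
  u$dir <- sample(c(-1L, 1L), n, replace = TRUE)
  mesh$units <- u
  key <- paste(u$layer, u$line, u$idx)
  linked <- setNames(logical(n), u$unit_id)
  links <- list()
  flagged <- character()

  sites <- unit_bead_sites(mesh)
  tips <- sites[sites$atom == "PS2", ]
  tip_xyz <- as.matrix(tips[order(tips$unit_id), c("x", "y", "z")])
  rownames(tip_xyz) <- sort(tips$unit_id)

  n_eligible <- 0L
  order_visit <- sample.int(n)
  for (i in order_visit) {
    interlayer <- mesh$layers > 1 && runif(1) < params$P_l
    if (interlayer) {
      dl <- if (params$l_direction == "up") 1L else -1L
      tgt <- paste((u$layer[i] + dl) %% mesh$layers, u$line[i], u$idx[i])
    } else {
      tgt <- paste(u$layer[i], (u$line[i] + u$dir[i]) %% mesh$n_lines, u$idx[i])
    }
    j <- match(tgt, key)
    if (is.na(j) || j == i) next
    pk <- paste(min(u$unit_id[i], u$unit_id[j]), max(u$unit_id[i], u$unit_id[j]))
    if (pk %in% flagged) next
    flagged <- c(flagged, pk)
    # steric reach between stem tips under PBC
    dv <- tip_xyz[as.character(u$unit_id[i]), ] - tip_xyz[as.character(u$unit_id[j]), ]
    dv <- dv - round(dv / mesh$cell) * mesh$cell
    if (vnorm(dv) > reach) next
    if (linked[as.character(u$unit_id[i])]) next
    if (linked[as.character(u$unit_id[j])] && runif(1) >= params$P_o) next
    kind <- if (interlayer) "interlayer"
            else if (linked[as.character(u$unit_id[j])]) "oligomer" else "dimer"
    n_eligible <- n_eligible + 1L
    if (runif(1) < params$P_cl) {
      links[[length(links) + 1L]] <- tibble(unit1 = u$unit_id[i],
                                            unit2 = u$unit_id[j], kind = kind)
      linked[as.character(u$unit_id[i])] <- TRUE
      linked[as.character(u$unit_id[j])] <- TRUE
    }
  }
  mesh$crosslinks <- if (length(links)) dplyr::bind_rows(links) else
    tibble(unit1 = integer(), unit2 = integer(), kind = character())
  mesh$flagged <- flagged
  attr(mesh, "n_eligible") <- n_eligible
  mesh
}

#' Relax a mesh with damped spring dynamics
#'
#' Builds the simplified per-layer spring network (one node per unit, bonds
#' along the glycan backbone and across peptide cross-links) and runs damped
#' velocity-Verlet dynamics on all layers simultaneously under periodic
#' boundaries. At fixed intervals the net extensional/compressional strain
#' on the bonds is used to rescale the in-plane cell lengths (positions
#' rescale affinely), so a stretched mesh relaxes both internally and
#' globally. When a protein is present, units are repelled from it so no
#' unit ends closer than the clearance.
#'
#' @param mesh a `pg_mesh`.
#' @param spring_params list: `k` bond stiffness, `dt` time step, `damping`
#'   velocity retention per step, `cell_every` steps between cell
#'   adjustments, `cell_gain` rescaling gain, `k_rep` protein repulsion
#'   stiffness.
#' @param max_steps iteration cap.
#' @param tol mean |strain| termination threshold (default 0.002).
#' @param protein optional [cg_protein()] in the mesh frame.
#' @param clearance protein clearance, nm.
#' @param seed unused; accepted for interface symmetry.
#' @return the relaxed mesh (positions and `cell` updated); attributes
#'   `mean_strain` and `steps_run` record the outcome.
#' @export
relax_mesh <- function(mesh, spring_params = list(), max_steps = 2000,
                       tol = 0.002, protein = NULL, clearance = 0.5,
                       seed = 1) {
  sp <- utils::modifyList(list(k = 50, k_bend = 60, dt = 0.02, damping = 0.85,
                               cell_every = 20, cell_gain = 0.5,
                               k_rep = 100), spring_params)
  u <- mesh$units
  if (!nrow(u)) abort("cannot relax an empty mesh")
  nb <- strand_neighbors(mesh)
  bonds <- rbind(
    data.frame(a = match(nb$unit1, u$unit_id), b = match(nb$unit2, u$unit_id),
               r0 = mesh$unit_length),
    if (nrow(mesh$crosslinks))
      data.frame(a = match(mesh$crosslinks$unit1, u$unit_id),
                 b = match(mesh$crosslinks$unit2, u$unit_id),
                 r0 = ifelse(mesh$crosslinks$kind == "interlayer",
                             mesh$layer_spacing, mesh$strand_spacing))
  )
  if (!nrow(bonds)) abort("mesh has no bonds to relax")
  X <- as.matrix(u[, c("x", "y", "z")])
  V <- matrix(0, nrow(X), 3)
  cell <- mesh$cell
  # glycan strands are stiff: straightening triplets (consecutive backbone
  # bonds sharing a middle unit) suppress floppy-chain wiggles
  nbb <- bonds[bonds$r0 == mesh$unit_length, , drop = FALSE]
  adj <- split(c(nbb$b, nbb$a), c(nbb$a, nbb$b))
  trip <- do.call(rbind, lapply(names(adj), function(m) {
    nb2 <- adj[[m]]
    if (length(nb2) == 2) c(nb2[1], as.integer(m), nb2[2]) else NULL
  }))
  pxyz <- if (!is.null(protein)) coords(protein)
  mean_strain <- Inf
  steps <- 0L
  for (s in seq_len(max_steps)) {
    steps <- s
    dvec <- X[bonds$a, , drop = FALSE] - X[bonds$b, , drop = FALSE]
    dvec <- dvec - sweep(round(sweep(dvec, 2, cell, "/")), 2, cell, "*")
    dlen <- sqrt(rowSums(dvec^2))
    dlen[dlen < 1e-9] <- 1e-9
    strain <- (dlen - bonds$r0) / bonds$r0
    mean_strain <- mean(abs(strain))
    # per-axis net strain must also settle, or a sparsely-bonded axis could
    # stay stretched while abundant bonds on the other axis dominate the mean
    ax_strain <- vapply(1:2, function(d) {
      wgt <- abs(dvec[, d]) / dlen
      sum(strain * wgt) / max(sum(wgt), 1e-9)
    }, numeric(1))
    if (mean_strain <= tol && all(abs(ax_strain) <= tol) && s > 1) break
    fmag <- -sp$k * (dlen - bonds$r0) / dlen
    Fb <- dvec * fmag
    F <- matrix(0, nrow(X), 3)
    for (d in 1:3) {
      F[, d] <- F[, d] + tabulate2(bonds$a, Fb[, d], nrow(X)) -
        tabulate2(bonds$b, Fb[, d], nrow(X))
    }
    if (!is.null(trip) && sp$k_bend > 0) {
      va <- X[trip[, 1], , drop = FALSE] - X[trip[, 2], , drop = FALSE]
      vb <- X[trip[, 3], , drop = FALSE] - X[trip[, 2], , drop = FALSE]
      va <- va - sweep(round(sweep(va, 2, cell, "/")), 2, cell, "*")
      vb <- vb - sweep(round(sweep(vb, 2, cell, "/")), 2, cell, "*")
      dev <- va + vb                      # zero when the triplet is straight
      for (d in 1:3) {
        F[, d] <- F[, d] - sp$k_bend * tabulate2(trip[, 1], dev[, d], nrow(X))
        F[, d] <- F[, d] - sp$k_bend * tabulate2(trip[, 3], dev[, d], nrow(X))
        F[, d] <- F[, d] + 2 * sp$k_bend * tabulate2(trip[, 2], dev[, d], nrow(X))
      }
    }
    if (!is.null(pxyz)) {
      dmin <- cpp_min_dist(X, pxyz)
      push <- which(dmin < clearance)
      for (i in push) {
        d2 <- sweep(pxyz, 2, X[i, ])
        j <- which.min(rowSums(d2^2))
        dir <- X[i, ] - pxyz[j, ]
        nd <- vnorm(dir)
        if (nd > 1e-9)
          F[i, ] <- F[i, ] + sp$k_rep * (clearance - dmin[i]) * dir / nd
      }
    }
    V <- sp$damping * V + sp$dt * F
    X <- X + sp$dt * V
    if (s %% sp$cell_every == 0) {
      for (d in 1:2) {
        wgt <- abs(dvec[, d]) / dlen
        saxis <- sum(strain * wgt) / max(sum(wgt), 1e-9)
        # stretched bonds (positive strain) shrink the cell, compressed grow it
        fac <- 1 - sp$cell_gain * max(-0.05, min(0.05, saxis))
        cell[d] <- cell[d] * fac
        X[, d] <- X[, d] * fac
      }
    }
  }
  if (any(!is.finite(X))) abort("non-finite positions during relaxation")
  mesh$units$x <- X[, 1]; mesh$units$y <- X[, 2]; mesh$units$z <- X[, 3]
  mesh$cell <- cell
  attr(mesh, "mean_strain") <- mean_strain
  attr(mesh, "steps_run") <- steps
  mesh
}

# sum `values` into bins given by `index` (signed scatter-add)
tabulate2 <- function(index, values, n) {
  out <- numeric(n)
  agg <- rowsum(values, index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
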