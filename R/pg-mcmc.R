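#' Gaussian-mixture target for glycan strand lengths
#'
#' Strand length distributions differ widely between bacterial species, so
#' the builder matches a user-defined sum of Gaussians over strand length
#' (in murein units), discretized at one-unit bins.
#'
#' @param weight,mean,sd equal-length vectors: mixture weights (normalized
#'   internally), means and standard deviations in units.
#' @param K_t MCMC acceptance temperature constant (default 0.05).
#' @return a `length_target`.
#' @export
length_target <- function(weight = 1, mean = 8, sd = 2, K_t = 0.05) {
  if (any(sd <= 0)) abort("mixture `sd` must be > 0")
  if (any(weight < 0) || sum(weight) <= 0) abort("mixture weights must be >= 0, sum > 0")
  structure(list(weight = weight / sum(weight), mean = mean, sd = sd, K_t = K_t),
            class = "length_target")
}

target_density <- function(target, lengths) {
  d <- numeric(length(lengths))
  for (k in seq_along(target$weight))
    d <- d + target$weight[k] * stats::dnorm(lengths, target$mean[k], target$sd[k])
  d
}

# KL(current || target) over 1-unit bins with additive smoothing
kl_divergence <- function(counts, target_p, smooth = 1e-6) {
  p <- counts + smooth; p <- p / sum(p)
  q <- target_p + smooth; q <- q / sum(q)
  sum(p * log(p / q))
}

# per-line helpers -----------------------------------------------------------
# a line is the full lattice row 0..L-1; present marks surviving units, cut
# marks severed bonds (bond i joins idx i and (i+1) mod L). Strand lengths
# count runs of present units between cuts; an intact cyclic line counts as
# one full-cell-length strand.
line_strand_lengths <- function(present, cut, L) {
  npres <- sum(present)
  if (npres == 0L) return(integer())
  eff_cut <- cut | !present | !present[c(2:L, 1)]
  if (!any(eff_cut)) return(npres)          # intact cycle: full length
  start <- (which(eff_cut)[1] %% L) + 1L
  rot <- ((start - 1L + seq_len(L) - 1L) %% L) + 1L
  grp <- cumsum(c(1L, utils::head(eff_cut[rot], -1L)))
  len <- tabulate(grp[present[rot]])
  len[len > 0L]
}

#' Match the strand length distribution by MCMC
#'
#' Runs a Markov chain whose moves break a random strand at a random bond or
#' rejoin two strand ends on the same lattice line. A move with proposed
#' Kullback-Leibler divergence K from the target (the last accepted value
#' being K_p) is accepted with probability
#' `max(0, 1 - exp((K - K_p) / K_t))`: improving moves are accepted with
#' probability approaching one, worsening moves are rejected. After the
#' chain, any strand still spanning the entire cell is broken in two (under
#' periodic boundaries this turns an effectively infinite strand into
#' finite ones). Break/join moves never create or destroy units.
#'
#' @param mesh a `pg_mesh`.
#' @param target a [length_target()].
#' @param steps number of MCMC steps (default 20000).
#' @param seed RNG seed.
#' @return the mesh with updated strand ids; attributes `kl_initial`,
#'   `kl_final` and `kl_trace` (accepted K values) record the chain.
#' @export
match_length_distribution <- function(mesh, target, steps = 20000, seed = 1) {
  if (steps < 0) abort("`steps` must be >= 0")
  L <- mesh$n_units_per_line
  tp <- target_density(target, seq_len(L))
  if (sum(tp) < 1e-12)
    abort("length target has zero probability over achievable lengths (1..cell length)")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  u <- mesh$units
  lk <- paste(u$layer, u$line)
  line_keys <- unique(lk)
  nl <- length(line_keys)
  present <- matrix(FALSE, nl, L)
  cut <- matrix(FALSE, nl, L)
  for (li in seq_len(nl)) {
    rows <- which(lk == line_keys[li])
    present[li, u$idx[rows] + 1L] <- TRUE
    # recover existing cuts from strand ids
    for (r in rows) {
      j <- which(u$idx[rows] == (u$idx[r] + 1L) %% L)
      if (length(j) && u$strand_id[rows[j]] != u$strand_id[r] &&
          (u$idx[r] + 1L) %% L == u$idx[rows[j]])
        cut[li, u$idx[r] + 1L] <- TRUE
    }
  }

  line_len <- vector("list", nl)
  counts <- integer(L)
  for (li in seq_len(nl)) {
    line_len[[li]] <- line_strand_lengths(present[li, ], cut[li, ], L)
    counts <- counts + tabulate(line_len[[li]], nbins = L)
  }
  K_p <- kl_divergence(counts, tp)
  kl_init <- K_p
  trace <- K_p

  if (steps > 0) for (s in seq_len(steps)) {
    li <- sample.int(nl, 1)
    cutv <- cut[li, ]
    do_break <- runif(1) < 0.5
    if (do_break) {
      # breakable bonds: not yet cut, both endpoints present
      cand <- which(!cutv & present[li, ] & present[li, c(2:L, 1)])
      if (!length(cand)) next
      # a cyclic (effectively infinite) strand is broken in two: one cut
      # alone would leave the length histogram unchanged
      eff <- cutv | !present[li, ] | !present[li, c(2:L, 1)]
      n_new <- if (!any(eff)) min(2L, length(cand)) else 1L
      b <- cand[sample.int(length(cand), n_new)]
      cutv[b] <- TRUE
    } else {
      cand <- which(cutv)
      if (!length(cand)) next
      b <- cand[sample.int(length(cand), 1)]
      cutv[b] <- FALSE
    }
    new_len <- line_strand_lengths(present[li, ], cutv, L)
    new_counts <- counts - tabulate(line_len[[li]], nbins = L) +
      tabulate(new_len, nbins = L)
    K <- kl_divergence(new_counts, tp)
    if (runif(1) < max(0, 1 - exp((K - K_p) / target$K_t))) {
      cut[li, ] <- cutv
      line_len[[li]] <- new_len
      counts <- new_counts
      K_p <- K
      trace <- c(trace, K)
    }
  }

  # final pass: no strand may still span the entire cell
  for (li in seq_len(nl)) {
    while (any(line_strand_lengths(present[li, ], cut[li, ], L) == L)) {
      cand <- which(!cut[li, ] & present[li, ] & present[li, c(2:L, 1)])
      if (!length(cand)) break
      cut[li, cand[sample.int(length(cand), 1)]] <- TRUE
    }
    counts <- counts - tabulate(line_len[[li]], nbins = L)
    line_len[[li]] <- line_strand_lengths(present[li, ], cut[li, ], L)
    counts <- counts + tabulate(line_len[[li]], nbins = L)
  }

  # write strand ids back from the cut sets
  sid <- integer(nrow(u)); nxt <- 0L
  for (li in seq_len(nl)) {
    rows <- which(lk == line_keys[li])
    idx <- u$idx[rows]
    eff_cut <- cut[li, ] | !present[li, ] | !present[li, c(2:L, 1)]
    if (!any(eff_cut)) {
      nxt <- nxt + 1L
      sid[rows] <- nxt
      next
    }
    start <- (which(eff_cut)[1] %% L)          # 0-based first idx after a cut
    pos <- ((seq_len(L) - 1L) - start) %% L    # rotation rank of each idx
    bump <- cumsum(c(1L, utils::head(eff_cut[((start + seq_len(L) - 1L) %% L) + 1L], -1L)))
    grp_of_idx <- integer(L)
    grp_of_idx[((start + seq_len(L) - 1L) %% L) + 1L] <- bump
    sid[rows] <- nxt + grp_of_idx[idx + 1L]
    nxt <- nxt + max(grp_of_idx[idx + 1L])
  }
  mesh$units$strand_id <- sid
  attr(mesh, "kl_initial") <- kl_init
  attr(mesh, "kl_final") <- kl_divergence(counts, tp)
  attr(mesh, "kl_trace") <- trace
  mesh
}
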