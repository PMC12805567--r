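#' Bead-pair interaction tables
#'
#' An interaction table stores, for every pair of coarse-grained bead types,
#' the depth \eqn{\epsilon(T_A, T_B)} (kJ/mol) and radius \eqn{\sigma} (nm) of
#' the Lennard-Jones minimum between beads of those types. The mean-field
#' membrane potential is built entirely from these pairwise minima: a probe
#' bead sitting in solvent, head-group or tail zone contributes
#' \eqn{-\epsilon(T_A, T_{zone})}.
#'
#' Two tables are bundled as editable CSV files: a Martini-3-style table used
#' for the membrane field (`"bundled_m3"`) and a Martini-2-style table used
#' for the peptidoglycan-layer field (`"bundled_m2"`). Both are synthetic
#' reconstructions over a reduced 13-type alphabet. A tiny `"toy"` table is
#' provided for tests and examples.
#'
#' @param source one of `"bundled_m3"`, `"bundled_m2"`, `"toy"`, or the path
#'   to a CSV/whitespace table with columns `typeA, typeB, epsilon, sigma`.
#' @param water_type name of the bead type representing bulk solvent.
#'
#' @return An object of class `interaction_table`: a list with a tibble of
#'   pairs (`$pairs`), fast lookup matrices `$eps` and `$sigma`, the
#'   `$water_type`, the type alphabet `$types` and a `$source_label`.
#' @examples
#' tab <- build_interaction_table("bundled_m3")
#' lj_min_energy("C1", "W", tab)
#' @export
build_interaction_table <- function(source = "bundled_m3", water_type = "W") {
  path <- switch(source,
    bundled_m3 = system.file("extdata", "interactions_m3.csv", package = "memorient"),
    bundled_m2 = system.file("extdata", "interactions_m2_pg.csv", package = "memorient"),
    toy = NULL,
    source
  )
  if (identical(source, "toy")) {
    df <- tibble(
      typeA = c("P", "P", "W", "C", "C", "C"),
      typeB = c("W", "P", "W", "W", "C", "P"),
      epsilon = c(5.0, 5.0, 5.0, 2.0, 3.5, 2.2),
      sigma = 0.47
    )
    label <- "toy"
  } else {
    if (!file.exists(path)) abort(sprintf("interaction table file not found: %s", path))
    df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE,
                          stringsAsFactors = FALSE)
    if (!all(c("typeA", "typeB", "epsilon", "sigma") %in% names(df)))
      abort("interaction table must have columns typeA, typeB, epsilon, sigma")
    df <- as_tibble(df)
    label <- if (source %in% c("bundled_m3", "bundled_m2")) source else basename(path)
  }
  if (any(!is.finite(df$epsilon)) || any(df$epsilon <= 0))
    abort("interaction table validation: all epsilon must be finite and > 0")
  if (any(!is.finite(df$sigma)) || any(df$sigma <= 0))
    abort("interaction table validation: all sigma must be finite and > 0")

  types <- sort(unique(c(df$typeA, df$typeB)))
  eps <- matrix(NA_real_, length(types), length(types), dimnames = list(types, types))
  sig <- eps
  for (i in seq_len(nrow(df))) {
    a <- df$typeA[i]; b <- df$typeB[i]
    e0 <- eps[a, b]
    if (!is.na(e0) && (e0 != df$epsilon[i] || sig[a, b] != df$sigma[i]))
      abort(sprintf("interaction table validation: conflicting entries for pair (%s, %s)", a, b))
    eps[a, b] <- eps[b, a] <- df$epsilon[i]
    sig[a, b] <- sig[b, a] <- df$sigma[i]
  }
  if (!water_type %in% types)
    abort(sprintf("water type '%s' absent from interaction table", water_type))
  structure(
    list(pairs = df, eps = eps, sigma = sig, types = types,
         water_type = water_type, source_label = label),
    class = "interaction_table"
  )
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("<interaction_table '%s': %d bead types, water = '%s'>\n",
              x$source_label, length(x$types), x$water_type))
  invisible(x)
}

table_lookup <- function(table, a, b, what = c("eps", "sigma")) {
  what <- match.arg(what)
  m <- table[[what]]
  bad <- !(a %in% table$types) | !(b %in% table$types)
  if (any(bad)) {
    miss <- unique(c(a[!(a %in% table$types)], b[!(b %in% table$types)]))
    abort(sprintf("bead type(s) missing from interaction table: %s",
                  paste(miss, collapse = ", ")))
  }
  v <- m[cbind(a, b)]
  if (any(is.na(v)))
    abort(sprintf("no interaction entry for pair (%s, %s)", a[is.na(v)][1], b[is.na(v)][1]))
  v
}

#' Minimum of the Lennard-Jones pair potential
#'
#' For \eqn{U_{\epsilon,\sigma}(r) = 4\epsilon((\sigma/r)^{12} - (\sigma/r)^6)}
#' the minimum value is \eqn{-\epsilon}, attained at \eqn{r = 2^{1/6}\sigma}.
#' The mean-field zone plateaus are these minima.
#'
#' @param type_a,type_b bead type names.
#' @param table an [build_interaction_table()] object.
#' @return A one-row tibble with `energy` (kJ/mol, equal to \eqn{-\epsilon})
#'   and `r_min` (nm).
#' @export
lj_min_energy <- function(type_a, type_b, table) {
  e <- table_lookup(table, type_a, type_b, "eps")
  s <- table_lookup(table, type_a, type_b, "sigma")
  tibble(type_a = type_a, type_b = type_b, energy = -e, r_min = 2^(1 / 6) * s)
}

#' Read the bundled bead-name mapping
#'
#' Maps `(resname, atom)` pairs in a CG structure file to bead types and
#' charges. The mapping ships as an editable two-column-plus text file;
#' unknown bead names are an error (silent skipping would corrupt the
#' potential).
#'
#' @param path mapping file; default the bundled file.
#' @return tibble with columns `resname`, `atom`, `type`, `charge`.
#' @export
read_bead_mapping <- function(path = NULL) {
  path <- path %||% system.file("extdata", "bead_mapping.tsv", package = "memorient")
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("resname", "atom", "type", "charge"),
                          stringsAsFactors = FALSE)
  as_tibble(df)
}
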