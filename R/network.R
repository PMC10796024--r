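#' Construct a bipartite plant-pollinator network
#'
#' A bipartite mutualistic network is stored as a binary incidence matrix
#' with plants on the rows and pollinators on the columns; entry `[i, l]`
#' is 1 iff plant `i` and pollinator `l` interact.
#'
#' @param incidence numeric matrix; any value `> 0` is binarized to 1.
#' @param plant_labels,pollinator_labels optional character vectors of
#'   species identifiers; default `P1..`, `A1..`.
#' @return An object of class `bipartite_network` with fields `incidence`,
#'   `n_plants`, `n_pollinators`, `plant_labels`, `pollinator_labels`.
#' @export
#' @examples
#' net <- bipartite_network(matrix(c(3, 0, 1, 2), 2, 2, byrow = TRUE))
#' plant_degrees(net)
bipartite_network <- function(incidence, plant_labels = NULL,
                              pollinator_labels = NULL) {
  if (!is.matrix(incidence) || !is.numeric(incidence))
    stop("incidence must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(incidence)) || any(incidence < 0))
    stop("incidence entries must be finite and non-negative", call. = FALSE)
  inc <- (incidence > 0) * 1
  np <- nrow(inc); na <- ncol(inc)
  plant_labels <- plant_labels %||%
    if (!is.null(rownames(incidence))) rownames(incidence)
    else paste0("P", seq_len(np))
  pollinator_labels <- pollinator_labels %||%
    if (!is.null(colnames(incidence))) colnames(incidence)
    else paste0("A", seq_len(na))
  if (length(plant_labels) != np) stop_dim("plant_labels", np,
                                           length(plant_labels))
  if (length(pollinator_labels) != na) stop_dim("pollinator_labels", na,
                                                length(pollinator_labels))
  dimnames(inc) <- list(plant_labels, pollinator_labels)
  structure(list(incidence = inc, n_plants = np, n_pollinators = na,
                 plant_labels = as.character(plant_labels),
                 pollinator_labels = as.character(pollinator_labels)),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite_network: %d plants x %d pollinators, %d links (connectance %.3f)\n",
              x$n_plants, x$n_pollinators, sum(x$incidence),
              if (x$n_plants * x$n_pollinators > 0)
                sum(x$incidence) / (x$n_plants * x$n_pollinators) else NA_real_))
  invisible(x)
}

#' Species degrees
#'
#' `plant_degrees()` returns row sums of the incidence matrix (number of
#' pollinator partners per plant); `pollinator_degrees()` returns column
#' sums.
#'
#' @param net a [bipartite_network()].
#' @return Named integer vector of degrees.
#' @export
plant_degrees <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  rowSums(net$incidence)
}

#' @rdname plant_degrees
#' @export
pollinator_degrees <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  colSums(net$incidence)
}

#' Degree-dependent mutualistic strength matrices
#'
#' Builds the directional mutualistic strength matrices. The strength plant
#' `i` receives from pollinator `l` is `gamma0 * eps[i, l] / g_i^delta`
#' where `g_i` is the degree of the receiving plant; the reciprocal strength
#' pollinator `j` receives from plant `n` divides by the pollinator degree
#' analogously. `delta = 0` gives every link the same strength `gamma0`;
#' `delta = 1` divides the per-capita strength fully among a species'
#' partners. Species with degree 0 get all-zero rows (no division by zero).
#'
#' @param net a [bipartite_network()].
#' @param params a [model_params()] (uses `gamma0` and `delta`).
#' @return A list of class `gamma_matrices` with `gamma_PA`
#'   (`n_plants x n_pollinators`) and `gamma_AP`
#'   (`n_pollinators x n_plants`).
#' @export
build_gamma <- function(net, params) {
  stopifnot(inherits(net, "bipartite_network"),
            inherits(params, "model_params"))
  resolve_params(params, net)  # dimension check of per-species vectors
  eps <- net$incidence
  gP <- rowSums(eps); gA <- colSums(eps)
  sP <- ifelse(gP > 0, params$gamma0 / gP^params$delta, 0)
  sA <- ifelse(gA > 0, params$gamma0 / gA^params$delta, 0)
  structure(list(gamma_PA = eps * sP,
                 gamma_AP = t(eps) * sA),
            class = "gamma_matrices")
}

#' Read a Web of Life style incidence matrix
#'
#' Parses a delimited (comma or tab) rectangular numeric matrix with plants
#' on the rows and pollinators on the columns. A non-numeric first row
#' and/or first column is treated as species labels. Cells may hold visit
#' counts; any value `> 0` becomes a link.
#'
#' @param path path to the delimited file.
#' @param sep field separator; `NULL` (default) tries comma then tab.
#' @return A [bipartite_network()].
#' @export
read_network <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty matrix in ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  cells <- strsplit(lines, sep, fixed = TRUE)
  nfield <- lengths(cells)
  if (length(unique(nfield)) != 1L)
    stop(sprintf("ragged rows in %s: line %d has %d fields, expected %d",
                 path, which(nfield != nfield[1])[1],
                 nfield[which(nfield != nfield[1])[1]], nfield[1]),
         call. = FALSE)
  tab <- do.call(rbind, lapply(cells, trimws))
  is_num <- function(v) !any(is.na(suppressWarnings(as.numeric(v))))
  first_row <- tab[1, , drop = TRUE]
  has_header <- if (ncol(tab) > 1) !is_num(first_row[-1]) else !is_num(first_row)
  first_col <- tab[, 1, drop = TRUE]
  if (has_header && length(first_col) > 1) first_col <- first_col[-1]
  has_rowlab <- !is_num(first_col)
  col_lab <- NULL; row_lab <- NULL
  if (has_header) {
    col_lab <- tab[1, , drop = TRUE]
    tab <- tab[-1, , drop = FALSE]
  }
  if (has_rowlab) {
    row_lab <- tab[, 1, drop = TRUE]
    tab <- tab[, -1, drop = FALSE]
    if (!is.null(col_lab)) col_lab <- col_lab[-1]
  }
  if (!nrow(tab) || !ncol(tab)) stop("empty matrix in ", path, call. = FALSE)
  suppressWarnings(m <- matrix(as.numeric(tab), nrow(tab), ncol(tab)))
  if (any(is.na(m))) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell in %s at data row %d, column %d",
                 path, bad[1], bad[2]), call. = FALSE)
  }
  bipartite_network(m, plant_labels = row_lab, pollinator_labels = col_lab)
}

#' Write a network as a delimited incidence matrix
#'
#' Writes the binary incidence matrix with pollinator labels as the header
#' row and plant labels as the first column, so that [read_network()]
#' round-trips the network exactly.
#'
#' @param net a [bipartite_network()].
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, sep = ",") {
  stopifnot(inherits(net, "bipartite_network"))
  header <- paste(c("species", net$pollinator_labels), collapse = sep)
  rows <- vapply(seq_len(net$n_plants), function(i)
    paste(c(net$plant_labels[i], net$incidence[i, ]), collapse = sep), "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Randomly remove a fraction of pollinators
#'
#' Models pollinator extinction pressure by deleting
#' `floor(fraction * n_pollinators)` pollinator columns chosen uniformly at
#' random, together with their links. Plants are always retained, even if
#' they become isolated. The floor rounding means that removing 80% of 61
#' pollinators retains 13.
#'
#' @param net a [bipartite_network()].
#' @param fraction proportion of pollinators to remove, in `[0, 1]`.
#' @param seed integer seed for the removal draw (`NULL` uses the session
#'   RNG).
#' @return The sub-network as a [bipartite_network()].
#' @export
remove_pollinators <- function(net, fraction, seed = NULL) {
  stopifnot(inherits(net, "bipartite_network"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]", call. = FALSE)
  n_rm <- floor(fraction * net$n_pollinators)
  if (n_rm == 0L) return(net)
  drop <- with_seed(seed, sample.int(net$n_pollinators, n_rm))
  keep <- setdiff(seq_len(net$n_pollinators), drop)
  bipartite_network(net$incidence[, keep, drop = FALSE],
                    plant_labels = net$plant_labels,
                    pollinator_labels = net$pollinator_labels[keep])
}

#' Generate a random bipartite network
#'
#' Draws links independently with expected density `connectance`. With
#' `heterogeneity > 0`, each species receives a lognormal propensity weight
#' (`exp(heterogeneity * z)`, `z` standard normal) and the link probability
#' of a pair is proportional to the product of its two weights (rescaled to
#' keep the expected connectance, capped at 1), producing a
#' generalist/specialist degree mix. `heterogeneity = 0` gives i.i.d.
#' Bernoulli links.
#'
#' @param n_plants,n_pollinators positive integers.
#' @param connectance expected link density in `(0, 1]`.
#' @param heterogeneity non-negative degree-heterogeneity strength
#'   (default 0).
#' @param seed integer seed; the same seed always returns the same network.
#' @return A [bipartite_network()].
#' @export
generate_network <- function(n_plants, n_pollinators, connectance,
                             heterogeneity = 0, seed = NULL) {
  if (n_plants < 1 || n_pollinators < 1)
    stop("network sizes must be >= 1", call. = FALSE)
  if (connectance <= 0 || connectance > 1)
    stop("connectance must lie in (0, 1]", call. = FALSE)
  if (heterogeneity < 0) stop("heterogeneity must be >= 0", call. = FALSE)
  inc <- with_seed(seed, {
    if (heterogeneity > 0) {
      v <- exp(heterogeneity * stats::rnorm(n_plants))
      w <- exp(heterogeneity * stats::rnorm(n_pollinators))
      p <- outer(v, w)
      p <- pmin(connectance * p / mean(p), 1)
    } else {
      p <- matrix(connectance, n_plants, n_pollinators)
    }
    matrix(stats::rbinom(n_plants * n_pollinators, 1, p),
           n_plants, n_pollinators)
  })
  bipartite_network(inc)
}
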