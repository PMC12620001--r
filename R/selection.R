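#' Parent selection strategies
#'
#' Three predetermined truncation strategies of decreasing intensity:
#' \describe{
#'   \item{SI1}{the n (default 15) individuals with the highest weighted
#'     breeding value;}
#'   \item{SI2}{hierarchical clustering of individual marker dosages
#'     (Euclidean distance, Ward linkage) into n_clusters (default 25)
#'     groups, then the top-WBV individual of each cluster;}
#'   \item{SI3}{as SI1 with n = 50.}
#' }
#' Ranking ties are broken by the lower row index; selection is
#' deterministic given the population.
#'
#' @param pop a `population` (or N x 2m matrix).
#' @param trait a `trait_arch`.
#' @param p minor allele frequencies (length m); defaults to the
#'   population's own.
#' @param n number of parents for SI1/SI3.
#' @param n_clusters number of clusters for SI2.
#' @return object of class `selection_result` with fields `indices`
#'   (increasing order), `n`, `strategy`.
#' @name selection
NULL

new_selection_result <- function(indices, strategy) {
  structure(list(indices = as.integer(indices), n = length(indices),
                 strategy = strategy),
            class = "selection_result")
}

top_by_wbv <- function(wbv, n) {
  # largest first, ties by lower index
  sort(order(-wbv, seq_along(wbv))[seq_len(n)])
}

#' @rdname selection
#' @export
select_si1 <- function(pop, trait, p = NULL, n = 15L) {
  w <- if (inherits(pop, "population")) pop$w else as.matrix(pop)
  if (n > nrow(w)) stop("n exceeds population size")
  wbv <- wbv_individual(w, trait, p %||% minor_allele_freq(w))
  new_selection_result(top_by_wbv(wbv, n), "SI1")
}

#' @rdname selection
#' @export
select_si2 <- function(pop, trait, p = NULL, n_clusters = 25L) {
  w <- if (inherits(pop, "population")) pop$w else as.matrix(pop)
  if (n_clusters > nrow(w)) stop("n_clusters exceeds population size")
  wbv <- wbv_individual(w, trait, p %||% minor_allele_freq(w))
  m <- ncol(w) %/% 2L
  dos <- w[, seq_len(m), drop = FALSE] + w[, m + seq_len(m), drop = FALSE]
  cl <- stats::cutree(stats::hclust(stats::dist(dos), method = "ward.D2"),
                      k = n_clusters)
  picks <- vapply(seq_len(n_clusters), function(k) {
    members <- which(cl == k)
    members[order(-wbv[members], members)[1L]]
  }, integer(1L))
  res <- new_selection_result(sort(picks), "SI2")
  res
}

#' @rdname selection
#' @export
select_si3 <- function(pop, trait, p = NULL, n = 50L) {
  res <- select_si1(pop, trait, p, n)
  res$strategy <- "SI3"
  res
}

# dispatcher used by the simulators; cfg is a scheme_config
select_parents <- function(w, trait, p, cfg) {
  switch(cfg$selection,
         SI1 = select_si1(w, trait, p, cfg$n_parents %||% 15L),
         SI2 = select_si2(w, trait, p, cfg$n_clusters %||% 25L),
         SI3 = select_si3(w, trait, p, cfg$n_parents %||% 50L),
         stop("unknown selection strategy: ", cfg$selection))
}

# number of parents a config selects (needed to size the noise bank)
selection_size <- function(cfg) {
  switch(cfg$selection,
         SI1 = cfg$n_parents %||% 15L,
         SI2 = cfg$n_clusters %||% 25L,
         SI3 = cfg$n_parents %||% 50L,
         stop("unknown selection strategy: ", cfg$selection))
}
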