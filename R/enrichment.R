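#' Heat-diffusion scores over a metabolite-pathway knowledge graph
#'
#' Places unit heat on each input compound and solves the regularized
#' Laplacian system \eqn{(L + \lambda I) f = b}, with \eqn{b} the indicator
#' of the input compounds. Scores are nonnegative (the system matrix is a
#' symmetric M-matrix) and decay with graph distance from the inputs; in the
#' \eqn{\lambda \to \infty} limit they become proportional to \eqn{b}.
#'
#' @param graph an undirected, connected igraph with vertex attribute `type`
#'   (`pathway`/`reaction`/`compound`).
#' @param input_compounds nonempty character vector of compound node ids.
#' @param lambda regularization (> 0; default 0.01).
#' @return named numeric vector of diffusion scores, one per node.
#' @export
diffusion_scores <- function(graph, input_compounds, lambda = 0.01) {
  b <- diffusion_input_vector(graph, input_compounds)
  M <- diffusion_system(graph, lambda)
  f <- as.numeric(Matrix::solve(M, b))
  stats::setNames(f, igraph::V(graph)$name)
}

diffusion_input_vector <- function(graph, input_compounds) {
  if (length(input_compounds) == 0) stop("input compound set is empty")
  nm <- igraph::V(graph)$name
  missing <- setdiff(input_compounds, nm)
  if (length(missing)) {
    stop("input ids not in the graph: ", paste(missing, collapse = ", "))
  }
  ty <- igraph::V(graph)$type
  not_cpd <- input_compounds[ty[match(input_compounds, nm)] != "compound"]
  if (length(not_cpd)) {
    stop("input ids are not compound nodes: ", paste(not_cpd, collapse = ", "))
  }
  as.numeric(nm %in% input_compounds)
}

diffusion_system <- function(graph, lambda) {
  if (lambda <= 0) stop("lambda must be positive")
  L <- igraph::laplacian_matrix(graph, weights = igraph::E(graph)$weight,
                                sparse = TRUE)
  L + lambda * Matrix::Diagonal(nrow(L))
}

#' Permutation p-scores for diffusion enrichment
#'
#' Ranks every node's diffusion score against a null distribution obtained by
#' diffusing from random compound sets of the same size. The p-score uses
#' add-one smoothing: \eqn{p = (1 + \#\{null \ge obs\}) / (1 + n)}; its lower
#' bound is therefore \eqn{1/(1+n)}. A z-score normal approximation of the
#' same null is available as `method = "normality"`.
#'
#' @inheritParams diffusion_scores
#' @param n_permutations number of random input sets (>= 1000).
#' @param seed integer seed.
#' @param method `"simulation"` (empirical, default) or `"normality"`
#'   (z-score against the permutation null's mean/sd).
#' @return an `enrichment_result` data.frame: `node`, `type`, `score`,
#'   `p_score`, `sig_0.01`, `sig_0.05`.
#' @export
pscore <- function(graph, input_compounds, n_permutations = 1000, seed = 1,
                   lambda = 0.01, method = c("simulation", "normality")) {
  method <- match.arg(method)
  if (n_permutations < 1000) stop("n_permutations must be >= 1000")
  b <- diffusion_input_vector(graph, input_compounds)
  nm <- igraph::V(graph)$name
  ty <- igraph::V(graph)$type
  compounds <- which(ty == "compound")
  k <- length(input_compounds)
  if (k > length(compounds)) {
    stop("input set larger than the number of compounds in the graph")
  }
  M <- diffusion_system(graph, lambda)
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(M))
  obs <- as.numeric(Matrix::solve(ch, b, system = "A"))
  B <- with_seed(seed, {
    cols <- replicate(n_permutations, {
      v <- numeric(length(nm))
      v[sample(compounds, k)] <- 1
      v
    })
    cols
  })
  null_scores <- as.matrix(Matrix::solve(ch, Matrix::Matrix(B, sparse = TRUE),
                                         system = "A"))
  p <- if (method == "simulation") {
    (1 + rowSums(null_scores >= obs)) / (1 + n_permutations)
  } else {
    mu <- rowMeans(null_scores)
    sd <- apply(null_scores, 1, stats::sd)
    z <- (obs - mu) / pmax(sd, .Machine$double.eps)
    stats::pnorm(z, lower.tail = FALSE)
  }
  structure(data.frame(node = nm, type = ty, score = obs, p_score = p,
                       sig_0.01 = p < 0.01, sig_0.05 = p < 0.05,
                       stringsAsFactors = FALSE),
            class = c("enrichment_result", "data.frame"),
            n_permutations = n_permutations, lambda = lambda, method = method)
}

#' Map significant features to knowledge-graph compounds
#'
#' Selects features below the raw p threshold, looks their identification
#' labels up in a compound dictionary, and returns the non-redundant compound
#' set (duplicates collapsed) plus the unmatched significant features.
#'
#' @param diff a `diff_result` from [fit_linear_model()].
#' @param features feature metadata (data.frame with `feature_id` and
#'   `identification`).
#' @param dictionary named character vector or two-column data.frame mapping
#'   identification labels to compound ids.
#' @param p_threshold raw p threshold for "significantly changed" (0.1).
#' @return list with `compounds` (unique compound ids) and `unmatched`
#'   (significant feature ids without a dictionary entry).
#' @export
map_features_to_compounds <- function(diff, features, dictionary,
                                      p_threshold = 0.1) {
  if (is.data.frame(dictionary)) {
    dictionary <- stats::setNames(as.character(dictionary[[2]]),
                                  as.character(dictionary[[1]]))
  }
  sig <- diff$feature_id[!is.na(diff$p_raw) & diff$p_raw < p_threshold]
  ident <- features$identification[match(sig, features$feature_id)]
  hit <- !is.na(ident) & nzchar(ident) & ident %in% names(dictionary)
  list(compounds = unique(unname(dictionary[ident[hit]])),
       unmatched = sig[!hit])
}
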