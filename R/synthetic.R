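#' Describe a planted period structure
#'
#' Defines the ground truth that the synthetic generators plant: the break
#' set, the binary gene-by-period activity plan, the intensity means inside
#' active (`mu_act > 0`) and inactive (`mu_inact < 0`) periods, the noise
#' level and one integer seed that drives every random draw.
#'
#' When no plan is supplied a random one is drawn and then repaired so that
#' every break flips at least one gene (a break no gene crosses would be
#' unidentifiable by construction).
#'
#' @param n_genes,n_times Dimensions of the planted instance.
#' @param tra_true Break indices in `1:(n_times - 1)`.
#' @param activity_plan Optional binary `n_genes x (length(tra_true) + 1)`
#'   matrix, one column per period.
#' @param mu_act,mu_inact Mean intensity in active / inactive cells
#'   (defaults +1 / -1).
#' @param sigma Intensity noise standard deviation (default 0.3).
#' @param seed Integer seed.
#' @return A `PlantedTruth` object.
#' @export
planted_truth <- function(n_genes, n_times, tra_true, activity_plan = NULL,
                          mu_act = 1, mu_inact = -1, sigma = 0.3, seed = 1L) {
  stopifnot(n_genes >= 1L, n_times >= 1L)
  tra_true <- validate_breaks(tra_true, n_times)
  if (!(mu_act > 0 && mu_inact < 0)) stop("need mu_act > 0 > mu_inact", call. = FALSE)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  n_periods <- length(tra_true) + 1L
  if (is.null(activity_plan)) {
    set.seed(seed)
    activity_plan <- matrix(sample(0:1, n_genes * n_periods, replace = TRUE),
                            n_genes, n_periods)
    for (b in seq_along(tra_true)) {
      if (all(activity_plan[, b] == activity_plan[, b + 1L])) {
        flip <- (b - 1L) %% n_genes + 1L
        activity_plan[flip, b + 1L] <- 1 - activity_plan[flip, b + 1L]
      }
    }
  }
  activity_plan <- as.matrix(activity_plan)
  if (!all(dim(activity_plan) == c(n_genes, n_periods))) {
    stop("activity plan must be ", n_genes, " x ", n_periods, call. = FALSE)
  }
  if (!all(activity_plan %in% c(0, 1))) stop("activity plan must be 0/1", call. = FALSE)
  structure(list(n_genes = n_genes, n_times = n_times, tra_true = tra_true,
                 activity_plan = activity_plan, mu_act = mu_act,
                 mu_inact = mu_inact, sigma = sigma, seed = as.integer(seed)),
            class = "PlantedTruth")
}

#' Generate an intensity matrix with planted period structure
#'
#' Each cell is drawn `Normal(mu_act, sigma)` where the plan marks the
#' gene active in that time point's period and `Normal(mu_inact, sigma)`
#' otherwise. Reproducible: the same truth (seed included) always yields
#' the same matrix.
#'
#' @param truth A [planted_truth()].
#' @param n_genes,n_times Optional; must match the truth when given.
#' @return List with the `IntensityMatrix` `M` and the `truth`.
#' @export
generate_intensity <- function(truth, n_genes = NULL, n_times = NULL) {
  stopifnot(inherits(truth, "PlantedTruth"))
  if (!is.null(n_genes) && n_genes != truth$n_genes) {
    stop("n_genes does not match the planted truth", call. = FALSE)
  }
  if (!is.null(n_times) && n_times != truth$n_times) {
    stop("n_times does not match the planted truth", call. = FALSE)
  }
  G <- truth$n_genes
  Tn <- truth$n_times
  period_of <- rep(seq_along(periods_from_breaks(truth$tra_true, Tn)),
                   lengths(periods_from_breaks(truth$tra_true, Tn)))
  mu <- ifelse(truth$activity_plan[, period_of, drop = FALSE] == 1,
               truth$mu_act, truth$mu_inact)
  set.seed(truth$seed)
  vals <- matrix(stats::rnorm(G * Tn, mean = mu, sd = truth$sigma), G, Tn,
                 dimnames = list(paste0("g", seq_len(G)), NULL))
  list(M = intensity_matrix(vals), truth = truth)
}

#' Generate a random acyclic regulatory network
#'
#' Samples `n_edges` distinct edges compatible with a random gene ordering,
#' so the result is always a DAG.
#'
#' @param n_genes Number of genes (`g1 ... gN`).
#' @param n_edges Number of edges; at most `n_genes * (n_genes - 1) / 2`,
#'   the maximum an acyclic orientation allows.
#' @param seed Integer seed.
#' @return A `RegulatoryNetwork`.
#' @export
generate_network <- function(n_genes, n_edges, seed = 1L) {
  max_edges <- n_genes * (n_genes - 1) / 2
  if (n_edges > max_edges) {
    stop("infeasible: at most ", max_edges, " acyclic edges for ", n_genes,
         " genes", call. = FALSE)
  }
  set.seed(seed)
  ord <- sample(n_genes)
  pairs <- which(upper.tri(matrix(0, n_genes, n_genes)), arr.ind = TRUE)
  pick <- pairs[sample(nrow(pairs), n_edges), , drop = FALSE]
  genes <- paste0("g", seq_len(n_genes))
  regulatory_network(data.frame(regulator = genes[ord[pick[, 1L]]],
                                target = genes[ord[pick[, 2L]]]))
}

signal_draw <- function(kind, n, scale) {
  switch(kind,
         randomwalk = cumsum(stats::rnorm(n, 0, scale)),
         ramp = stats::runif(1, 0.5, 1.5) * scale * seq(0, 4, length.out = n) *
           sample(c(-1, 1), 1),
         sine = scale * 2 * sin(2 * pi * seq_len(n) / n + stats::runif(1, 0, 2 * pi)))
}

#' Generate an expression profile with planted regulation periods
#'
#' Root genes (no regulators) follow the chosen signal. In periods where the
#' plan marks a regulated gene active, the gene is a positively weighted
#' linear combination of its parents plus noise; in inactive periods it
#' follows an independent draw of the same signal family plus noise, so it
#' carries no information about its parents there.
#'
#' @param network An acyclic `RegulatoryNetwork`; the number of regulated
#'   genes must equal `truth$n_genes`.
#' @param truth A [planted_truth()]; its plan rows map to the regulated
#'   genes in the order of [regulated_genes()].
#' @param parent_signal `"randomwalk"` (default), `"ramp"` or `"sine"`.
#' @param sigma_expr Expression noise standard deviation (default 0.1).
#' @param signal_scale Scale of the driving signals (default 1).
#' @return List with the `ExpressionProfile` and the `truth`.
#' @export
generate_expression <- function(network, truth,
                                parent_signal = c("randomwalk", "ramp", "sine"),
                                sigma_expr = 0.1, signal_scale = 1) {
  parent_signal <- match.arg(parent_signal)
  stopifnot(inherits(network, "RegulatoryNetwork"),
            inherits(truth, "PlantedTruth"))
  g <- as_igraph(network)
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership ==
                                    which(comp$csize > 1L)[1L]]
    stop("network contains a cycle through: ", paste(cyc, collapse = ", "),
         call. = FALSE)
  }
  reg <- regulated_genes(network)
  if (length(reg) != truth$n_genes) {
    stop("truth plans ", truth$n_genes, " regulated genes but the network has ",
         length(reg), call. = FALSE)
  }
  Tn <- truth$n_times
  all_genes <- network_genes(network)
  topo <- names(igraph::topo_sort(g))
  periods <- periods_from_breaks(truth$tra_true, Tn)

  set.seed(truth$seed)
  vals <- matrix(NA_real_, length(all_genes), Tn,
                 dimnames = list(all_genes, NULL))
  for (gene in topo) {
    pa <- parents(network, gene)
    if (length(pa) == 0L) {
      vals[gene, ] <- signal_draw(parent_signal, Tn, signal_scale) +
        stats::rnorm(Tn, 0, sigma_expr)
      next
    }
    plan <- truth$activity_plan[match(gene, reg), ]
    w <- stats::runif(length(pa), 0.7, 1.3)
    y <- numeric(Tn)
    for (p in seq_along(periods)) {
      idx <- periods[[p]]
      y[idx] <- if (plan[p] == 1) {
        drop(w %*% vals[pa, idx, drop = FALSE]) + stats::rnorm(length(idx), 0, sigma_expr)
      } else {
        signal_draw(parent_signal, length(idx), signal_scale) +
          stats::rnorm(length(idx), 0, sigma_expr)
      }
    }
    vals[gene, ] <- y
  }
  list(profile = expression_profile(vals), truth = truth)
}
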