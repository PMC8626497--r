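#' Parameters for the synthetic dendritic-spine population
#'
#' Six morphological classes are planted with fixed proportions. Counts per
#' class are apportioned deterministically (largest-remainder rounding), so
#' `proportions * n_spines` is recovered exactly whenever it is integral.
#'
#' @param n_spines number of spines to generate.
#' @param class_proportions nonnegative numeric of length 6 summing to 1, in
#'   the order `filopodia, long_thin, thin, stubby, mushroom, branched`.
#' @param dendrite_length_um dendritic segment length carrying the spines.
#' @param seed integer seed.
#' @return A validated list of class `spine_sim_params`.
#' @export
spine_sim_params <- function(n_spines = 600L,
                             class_proportions = c(filopodia = 0.15,
                                                   long_thin = 0.20,
                                                   thin = 0.20,
                                                   stubby = 0.20,
                                                   mushroom = 0.15,
                                                   branched = 0.10),
                             dendrite_length_um = 50,
                             seed = 1L) {
  pr <- as.numeric(class_proportions)
  if (length(pr) != 6L || any(pr < 0) || abs(sum(pr) - 1) > 1e-9)
    stop_gq("`class_proportions` must be 6 nonnegative values summing to 1")
  if (dendrite_length_um <= 0) stop_gq("`dendrite_length_um` must be positive")
  structure(list(n_spines = as.integer(n_spines),
                 class_proportions = stats::setNames(pr, spine_classes()),
                 dendrite_length_um = as.numeric(dendrite_length_um),
                 seed = as.integer(seed)),
            class = "spine_sim_params")
}

# Largest-remainder apportionment of n into parts proportional to p.
apportion <- function(n, p) {
  base <- floor(p * n)
  rem <- p * n - base
  short <- n - sum(base)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1L
  }
  as.integer(base)
}

#' Generate spine geometries with known classes
#'
#' Each spine's `(length, width, heads)` is drawn uniformly from a region
#' strictly interior to its class's decision cell under the default rule
#' precedence of [classify_spine()], so classification round-trips the truth
#' exactly. Rows are returned in shuffled order.
#'
#' @param params a [spine_sim_params()] object.
#' @return data frame with `length_um`, `width_um`, `heads`, `true_class`
#'   (factor over [spine_classes()]).
#' @export
generate_spine_set <- function(params) {
  stopifnot(inherits(params, "spine_sim_params"))
  n <- params$n_spines
  if (n == 0L)
    return(data.frame(length_um = numeric(0), width_um = numeric(0),
                      heads = integer(0),
                      true_class = factor(character(0),
                                          levels = spine_classes())))
  counts <- apportion(n, params$class_proportions)
  with_seed(params$seed, {
    draw <- function(klass, k) {
      if (k == 0L) return(NULL)
      geom <- switch(
        klass,
        filopodia = data.frame(length_um = runif(k, 2.05, 4.0),
                               width_um = runif(k, 0.10, 0.55),
                               heads = rep(1L, k)),
        long_thin = data.frame(length_um = runif(k, 1.05, 1.95),
                               width_um = runif(k, 0.15, 0.45),
                               heads = rep(1L, k)),
        thin = data.frame(length_um = runif(k, 0.40, 0.95),
                          width_um = runif(k, 0.10, 0.35),
                          heads = rep(1L, k)),
        stubby = {
          w <- runif(k, 0.35, 0.58)
          data.frame(length_um = w * runif(k, 0.40, 0.95),
                     width_um = w, heads = rep(1L, k))
        },
        mushroom = data.frame(length_um = runif(k, 0.70, 1.90),
                              width_um = runif(k, 0.65, 1.10),
                              heads = rep(1L, k)),
        branched = data.frame(length_um = runif(k, 0.50, 1.80),
                              width_um = runif(k, 0.20, 0.50),
                              heads = sample(2:3, k, replace = TRUE)))
      geom$true_class <- klass
      geom
    }
    out <- do.call(rbind, Map(draw, spine_classes(), counts))
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    rownames(out) <- NULL
    out$true_class <- factor(out$true_class, levels = spine_classes())
    out
  })
}
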