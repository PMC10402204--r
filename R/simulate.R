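#' The benchmark cell-type tree
#'
#' Stem cells S differentiate into two multipotent types A and B, which
#' differentiate into terminal types A1, A2 and B1, B2: a rooted tree of
#' depth 2 with 4 leaves. Intermediate states live on the edges.
#'
#' @return data.frame with columns `parent`, `child`, one row per edge.
#' @export
cell_type_tree <- function() {
  data.frame(
    parent = c("S", "S", "A", "A", "B", "B"),
    child = c("A", "B", "A1", "A2", "B1", "B2"),
    stringsAsFactors = FALSE
  )
}

#' Ideal expression profiles for the 7 cell types
#'
#' Draws one mean-expression (Poisson rate) vector per cell type by a random
#' walk down the tree: the root gets i.i.d. uniform baseline rates and each
#' child adds an independent Gaussian step of per-gene standard deviation
#' `separation` to its parent (clipped at zero). Distances therefore respect
#' the tree: a parent and child are one step apart while leaves on different
#' branches are four independent steps apart.
#'
#' @param n_genes number of genes G (>= 7; default 200).
#' @param separation per-gene step size between a parent and child profile
#'   (expression-rate units); 0 collapses all types onto the root profile.
#' @param baseline_range range of the root's uniform baseline rates.
#' @param seed integer seed; the global RNG state is restored on exit.
#' @return 7 x G matrix, rows S, A, B, A1, A2, B1, B2; all entries >= 0.
#' @export
make_ideal_profiles <- function(n_genes = 200, separation = 1.5,
                                baseline_range = c(2, 10), seed = 1) {
  if (n_genes < 7) stop("n_genes must be at least 7")
  if (separation < 0) stop("separation must be non-negative")
  with_seed(seed, {
    tree <- cell_type_tree()
    types <- c("S", unique(tree$child))
    prof <- matrix(0, length(types), n_genes,
                   dimnames = list(types, paste0("gene", seq_len(n_genes))))
    prof["S", ] <- stats::runif(n_genes, baseline_range[1], baseline_range[2])
    for (r in seq_len(nrow(tree))) {
      step <- stats::rnorm(n_genes, 0, 1) * separation
      prof[tree$child[r], ] <- pmax(prof[tree$parent[r], ] + step, 0)
    }
    prof
  })
}

#' Interpolated profile of a differentiating cell
#'
#' Gradual development along a tree edge is modelled as the convex
#' combination `theta * parent + (1 - theta) * child`: theta = 1 is the pure
#' parent type, theta = 0 the pure child.
#'
#' @param profiles matrix from [make_ideal_profiles()].
#' @param parent,child type names forming a tree edge.
#' @param theta mixing coefficient(s) in \[0, 1\].
#' @return length-G rate vector (or a matrix, one row per theta).
#' @export
mix_profile <- function(profiles, parent, child, theta) {
  if (!all(c(parent, child) %in% rownames(profiles))) {
    stop("unknown cell type: ", paste(setdiff(c(parent, child),
                                              rownames(profiles)), collapse = ", "))
  }
  if (any(theta < 0 | theta > 1)) stop("theta must lie in [0, 1]")
  p <- profiles[parent, ]
  q <- profiles[child, ]
  if (length(theta) == 1L) {
    theta * p + (1 - theta) * q
  } else {
    outer(theta, p) + outer(1 - theta, q)
  }
}

#' Ground-truth label of an interpolated state
#'
#' Cells close to an endpoint are labelled as the pure type; ambiguous cells
#' (theta near 0.5) get the transitional label `"Parent->Child"`.
#'
#' @param parent,child edge endpoints (vectors recycle against theta).
#' @param theta mixing coefficient(s) in \[0, 1\].
#' @param ambiguity_band `c(lo, hi)`: theta > hi labels the parent,
#'   theta < lo the child, anything in between is transitional.
#' @return character vector of labels.
#' @export
label_state <- function(parent, child, theta, ambiguity_band = c(0.25, 0.75)) {
  if (any(theta < 0 | theta > 1)) stop("theta must lie in [0, 1]")
  ifelse(theta > ambiguity_band[2], parent,
         ifelse(theta < ambiguity_band[1], child,
                paste0(parent, "->", child)))
}

#' Default 7-sample longitudinal benchmark design
#'
#' One sample on day 1 and two per day on days 2-4, each a mixture over tree
#' edges with a theta range encoding the sample's developmental stage:
#' \itemize{
#'   \item day 1: 80\% near-pure S (theta in \[0.9, 1\] on the S edges),
#'     20\% early transitional S->A / S->B (theta in \[0.5, 0.9\]);
#'   \item day 2: 50\% transitional S->A / S->B (theta in \[0.25, 0.75\]),
#'     50\% newly arrived A / B (theta in \[0, 0.1\] on the S edges);
#'   \item day 3: 50\% pure A / B about to differentiate (theta in \[0.9, 1\]
#'     on the terminal edges), 50\% transitional A->A1 etc.
#'     (theta in \[0.25, 0.75\]);
#'   \item day 4: 50\% transitional, 50\% terminal A1/A2/B1/B2
#'     (theta in \[0, 0.25\]).
#' }
#' Within a composition group, cells are spread evenly over the listed edges.
#' The two same-day samples share the same design (replicates differ only in
#' their batch shift and sampling noise).
#'
#' @return data.frame with one row per (sample, component): columns
#'   `sample_id`, `day`, `group`, `parent`, `child`, `theta_lo`, `theta_hi`,
#'   `fraction` (group fraction; within-group edge split is encoded by
#'   repeated rows with `fraction / n_edges`).
#' @export
benchmark_design <- function() {
  s_edges <- list(c("S", "A"), c("S", "B"))
  t_edges <- list(c("A", "A1"), c("A", "A2"), c("B", "B1"), c("B", "B2"))
  comp <- function(day, group, edges, lo, hi, frac) {
    do.call(rbind, lapply(edges, function(e) {
      data.frame(day = day, group = group, parent = e[1], child = e[2],
                 theta_lo = lo, theta_hi = hi,
                 fraction = frac / length(edges), stringsAsFactors = FALSE)
    }))
  }
  day_comp <- rbind(
    comp(1, "S", s_edges, 0.90, 1.00, 0.8),
    comp(1, "S->", s_edges, 0.50, 0.90, 0.2),
    comp(2, "S->", s_edges, 0.25, 0.75, 0.5),
    comp(2, "AB", s_edges, 0.00, 0.10, 0.5),
    comp(3, "AB", t_edges, 0.90, 1.00, 0.5),
    comp(3, "->T", t_edges, 0.25, 0.75, 0.5),
    comp(4, "->T", t_edges, 0.25, 0.75, 0.5),
    comp(4, "T", t_edges, 0.00, 0.25, 0.5)
  )
  samples <- data.frame(sample_id = paste0("sample", 1:7),
                        day = c(1, 2, 2, 3, 3, 4, 4))
  out <- merge(samples, day_comp, by = "day", sort = FALSE)
  out[order(out$sample_id), c("sample_id", "day", "group", "parent", "child",
                              "theta_lo", "theta_hi", "fraction")]
}

#' Simulate the longitudinal branching-differentiation benchmark
#'
#' Generates a cells x genes count matrix with known cell types, days and
#' batch effects. For each cell: a tree edge and a mixing coefficient theta
#' are drawn according to its sample's design; the rate vector is the
#' interpolated profile plus the sample's additive batch shift on a shared
#' random subset of susceptible genes plus i.i.d. Gaussian noise; counts are
#' Poisson draws from the rate clipped at zero. Cell numbers per design
#' component are allocated by hierarchical largest-remainder rounding
#' (first across composition groups, then across edges within a group), so
#' group fractions are exact whenever `n_cells_per_sample * fraction` is an
#' integer.
#'
#' @param design design data.frame as returned by [benchmark_design()].
#' @param profiles ideal profiles; default [make_ideal_profiles()] with
#'   `n_genes` and `seed`.
#' @param n_genes number of genes (default 200).
#' @param n_cells_per_sample cells per sample (default 500, i.e. 3,500 total).
#' @param susceptible_frac fraction of genes susceptible to the batch effect
#'   (default 0.2).
#' @param batch_sd standard deviation of the per-(sample, susceptible gene)
#'   additive shift (expression-rate units; default 3). 0 disables batch
#'   effects.
#' @param noise_sd standard deviation of per-cell, per-gene Gaussian noise
#'   added to the rate before Poisson sampling (default 1).
#' @param ambiguity_band passed to [label_state()].
#' @param seed integer seed; identical seeds give bit-identical benchmarks.
#'   The global RNG state is restored on exit.
#' @return object of class `"bcd_benchmark"`: list with `counts` (N x G
#'   integer matrix), `metadata` (data.frame: cell_id, sample_id, day,
#'   cell_type, parent, child, theta), `profiles`, `susceptible_genes`
#'   (gene indices), `shifts` (samples x genes matrix), `design`, `seed`.
#' @export
simulate_benchmark <- function(design = benchmark_design(),
                               profiles = NULL,
                               n_genes = 200,
                               n_cells_per_sample = 500,
                               susceptible_frac = 0.2,
                               batch_sd = 3,
                               noise_sd = 1,
                               ambiguity_band = c(0.25, 0.75),
                               seed = 1) {
  if (nrow(design) == 0L) stop("empty design")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (batch_sd < 0) stop("batch_sd must be non-negative")
  frac_ok <- tapply(design$fraction, design$sample_id, sum)
  if (any(abs(frac_ok - 1) > 1e-8)) {
    stop("composition fractions must sum to 1 within each sample")
  }
  if (is.null(profiles)) {
    profiles <- make_ideal_profiles(n_genes = n_genes, seed = seed)
  }
  G <- ncol(profiles)
  samples <- unique(design[, c("sample_id", "day")])
  S <- nrow(samples)
  with_seed(seed, {
    susceptible <- sort(sample.int(G, round(susceptible_frac * G)))
    shifts <- matrix(0, S, G, dimnames = list(samples$sample_id,
                                              colnames(profiles)))
    if (batch_sd > 0 && length(susceptible) > 0) {
      shifts[, susceptible] <- stats::rnorm(S * length(susceptible), 0, batch_sd)
    }
    meta_list <- list()
    count_list <- list()
    for (si in seq_len(S)) {
      sid <- samples$sample_id[si]
      comp <- design[design$sample_id == sid, , drop = FALSE]
      n_comp <- allocate_cells(comp, n_cells_per_sample)
      for (ci in seq_len(nrow(comp))) {
        nc <- n_comp[ci]
        if (nc == 0L) next
        theta <- stats::runif(nc, comp$theta_lo[ci], comp$theta_hi[ci])
        rates <- mix_profile(profiles, comp$parent[ci], comp$child[ci], theta)
        rates <- matrix(rates, nrow = nc)  # single-cell components stay 2-D
        rates <- sweep(rates, 2L, shifts[si, ], "+")
        if (noise_sd > 0) {
          rates <- rates + stats::rnorm(length(rates), 0, noise_sd)
        }
        rates[rates < 0] <- 0
        counts <- matrix(stats::rpois(length(rates), rates), nrow = nc)
        meta_list[[length(meta_list) + 1L]] <- data.frame(
          sample_id = sid, day = samples$day[si],
          cell_type = label_state(comp$parent[ci], comp$child[ci], theta,
                                  ambiguity_band),
          parent = comp$parent[ci], child = comp$child[ci], theta = theta,
          stringsAsFactors = FALSE
        )
        count_list[[length(count_list) + 1L]] <- counts
      }
    }
    counts <- do.call(rbind, count_list)
    metadata <- do.call(rbind, meta_list)
    metadata <- cbind(cell_id = sprintf("cell%05d", seq_len(nrow(metadata))),
                      metadata)
    dimnames(counts) <- list(metadata$cell_id, colnames(profiles))
    storage.mode(counts) <- "integer"
    structure(
      list(counts = counts, metadata = metadata, profiles = profiles,
           susceptible_genes = susceptible, shifts = shifts, design = design,
           seed = seed),
      class = "bcd_benchmark"
    )
  })
}

#' @export
print.bcd_benchmark <- function(x, ...) {
  cat("Synthetic differentiation benchmark:",
      nrow(x$counts), "cells x", ncol(x$counts), "genes,",
      nrow(x$shifts), "samples over days",
      paste(range(x$metadata$day), collapse = "-"), "\n")
  cat("  susceptible genes:", length(x$susceptible_genes),
      "| seed:", x$seed, "\n")
  print(table(x$metadata$sample_id, x$metadata$cell_type))
  invisible(x)
}

# hierarchical largest-remainder rounding: exact group totals first, then
# edges within each group
allocate_cells <- function(comp, n_cells) {
  groups <- unique(comp$group)
  gfrac <- vapply(groups, function(g) sum(comp$fraction[comp$group == g]),
                  numeric(1))
  gn <- largest_remainder(gfrac * n_cells)
  out <- integer(nrow(comp))
  for (gi in seq_along(groups)) {
    idx <- which(comp$group == groups[gi])
    w <- comp$fraction[idx] / sum(comp$fraction[idx])
    out[idx] <- largest_remainder(w * gn[gi])
  }
  out
}

largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- round(sum(x)) - sum(fl)
  if (rem > 0) {
    extra <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  as.integer(fl)
}

# evaluate `expr` under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
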