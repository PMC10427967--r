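#' Settings for the symbolic-regression engine
#'
#' Multi-restart genetic programming over expression trees with operators
#' `+`, `-`, `*`, protected `/` and `square`, feature and constant leaves.
#' Fitness is training R2 with a parsimony penalty proportional to node
#' count. Each restart archives its best expression per complexity level
#' (a Pareto-style elite), and the run stops early once an expression
#' reaches `early_stop_r2`.
#'
#' @param population population size per restart (default 200, >= 4).
#' @param generations generations per restart (default 50).
#' @param restarts independent restarts (default 30).
#' @param p_crossover,p_mutation genetic operator probabilities (remainder
#'   is reproduction).
#' @param tournament_size tournament selection size (default 3).
#' @param max_depth maximum depth of randomly generated trees (default 5).
#' @param max_nodes node-count ceiling for offspring; oversized children are
#'   replaced by their first parent (default 64).
#' @param parsimony fitness penalty per node (default 1e-3).
#' @param const_range range for random constant leaves.
#' @param early_stop_r2 stop a restart once some expression attains this
#'   training R2 (default 0.999).
#' @return an object of class `sr_settings`.
#' @export
sr_settings <- function(population = 200, generations = 50, restarts = 30,
                        p_crossover = 0.7, p_mutation = 0.2,
                        tournament_size = 3, max_depth = 5, max_nodes = 64,
                        parsimony = 1e-3, const_range = c(-2, 2),
                        early_stop_r2 = 0.999) {
  abort_if(population < 4, "population must be >= 4 (got %d)", population)
  abort_if(restarts < 1, "need >= 1 restart")
  structure(list(population = population, generations = generations,
                 restarts = restarts, p_crossover = p_crossover,
                 p_mutation = p_mutation, tournament_size = tournament_size,
                 max_depth = max_depth, max_nodes = max_nodes,
                 parsimony = parsimony, const_range = const_range,
                 early_stop_r2 = early_stop_r2), class = "sr_settings")
}

# ---- expression trees ------------------------------------------------------
# node: list(op, args = list(...)); leaf: list(var = j) or list(const = c)

sr_node_count <- function(tree) {
  if (!is.null(tree$op))
    return(1L + sum(vapply(tree$args, sr_node_count, integer(1))))
  1L
}

sr_tree_vars <- function(tree) {
  if (!is.null(tree$var)) return(tree$var)
  if (!is.null(tree$op))
    return(unique(unlist(lapply(tree$args, sr_tree_vars))))
  integer(0)
}

protected_div <- function(num, den) {
  s <- ifelse(den >= 0, 1, -1)
  num / (s * pmax(abs(den), 1e-6))
}

sr_eval <- function(tree, X) {
  if (!is.null(tree$var)) return(X[, tree$var])
  if (!is.null(tree$const)) return(rep(tree$const, nrow(X)))
  a <- sr_eval(tree$args[[1]], X)
  switch(tree$op,
         "+" = a + sr_eval(tree$args[[2]], X),
         "-" = a - sr_eval(tree$args[[2]], X),
         "*" = a * sr_eval(tree$args[[2]], X),
         "/" = protected_div(a, sr_eval(tree$args[[2]], X)),
         "sq" = a * a)
}

sr_deparse <- function(tree, feature_ids) {
  if (!is.null(tree$var)) return(feature_ids[tree$var])
  if (!is.null(tree$const)) return(formatC(tree$const, format = "g"))
  a <- sr_deparse(tree$args[[1]], feature_ids)
  if (tree$op == "sq") return(paste0("sq(", a, ")"))
  b <- sr_deparse(tree$args[[2]], feature_ids)
  if (tree$op == "/") return(paste0("div(", a, ", ", b, ")"))
  paste0("(", a, " ", tree$op, " ", b, ")")
}

sr_random_leaf <- function(p, const_range) {
  if (runif(1) < 0.8) list(var = sample.int(p, 1))
  else list(const = runif(1, const_range[1], const_range[2]))
}

sr_random_tree <- function(p, depth, method, const_range) {
  if (depth <= 0 || (method == "grow" && runif(1) < 0.3))
    return(sr_random_leaf(p, const_range))
  op <- sample(c("+", "-", "*", "/", "sq"), 1)
  nargs <- if (op == "sq") 1 else 2
  list(op = op,
       args = lapply(seq_len(nargs), function(i)
         sr_random_tree(p, depth - 1, method, const_range)))
}

# get/replace the k-th node in preorder
sr_get_node <- function(tree, k) {
  env <- new.env(); env$i <- 0L; env$found <- NULL
  walk <- function(nd) {
    if (!is.null(env$found)) return()
    env$i <- env$i + 1L
    if (env$i == k) { env$found <- nd; return() }
    if (!is.null(nd$op)) for (a in nd$args) walk(a)
  }
  walk(tree)
  env$found
}

sr_set_node <- function(tree, k, new) {
  env <- new.env(); env$i <- 0L
  walk <- function(nd) {
    env$i <- env$i + 1L
    if (env$i == k) return(new)
    if (!is.null(nd$op))
      nd$args <- lapply(nd$args, walk)
    nd
  }
  walk(tree)
}

sr_crossover <- function(a, b) {
  ka <- sample.int(sr_node_count(a), 1)
  kb <- sample.int(sr_node_count(b), 1)
  sr_set_node(a, ka, sr_get_node(b, kb))
}

sr_mutate <- function(a, p, const_range) {
  k <- sample.int(sr_node_count(a), 1)
  sr_set_node(a, k, sr_random_tree(p, 2, "grow", const_range))
}

# R2 with the degenerate-response convention: constant y => 0
sr_r2 <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(0)
  if (any(!is.finite(yhat))) return(-Inf)
  1 - sum((y - yhat)^2) / sst
}

# ---- the engine ------------------------------------------------------------

#' Fit symbolic regression by multi-restart genetic programming
#'
#' Evolves expression trees predicting the potency score from features.
#' Ramped grow/full initialization, tournament selection, subtree crossover
#' and mutation, elitism of one, and a parsimony-penalized training-R2
#' fitness. Deterministic given `seed`.
#'
#' @param X line x feature matrix.
#' @param y a `composite_score` or named numeric vector.
#' @param settings an [sr_settings()].
#' @param seed integer seed.
#' @return an object of class `sr_run` with `archive`: a data.frame-like
#'   list of archived expressions (string form, complexity, training R2,
#'   variables used).
#' @export
sr_fit <- function(X, y, settings = sr_settings(), seed = 1) {
  stopifnot(inherits(settings, "sr_settings"))
  X <- as.matrix(X)
  y <- score_vector(y, rownames(X))
  abort_if(nrow(X) < 4, "symbolic regression needs >= 4 lines")
  p <- ncol(X)
  fids <- colnames(X) %||% paste0("x", seq_len(p))

  with_seed(seed, {
    archive <- list()  # keyed by complexity: best r2 expression at that size
    consider <- function(tree, r2) {
      cx <- sr_node_count(tree)
      key <- as.character(cx)
      if (is.null(archive[[key]]) || r2 > archive[[key]]$r2_train)
        archive[[key]] <<- list(tree = tree, complexity = cx, r2_train = r2)
    }
    for (rs in seq_len(settings$restarts)) {
      # ramped half-and-half initialization
      pop <- lapply(seq_len(settings$population), function(i) {
        d <- 2 + (i %% (settings$max_depth - 1))
        m <- if (i %% 2 == 0) "grow" else "full"
        sr_random_tree(p, d, m, settings$const_range)
      })
      evaluate <- function(pop) {
        vapply(pop, function(t) {
          r2 <- sr_r2(y, sr_eval(t, X))
          c(r2, r2 - settings$parsimony * sr_node_count(t))
        }, numeric(2))
      }
      sc <- evaluate(pop)
      for (i in seq_along(pop)) consider(pop[[i]], sc[1, i])
      stop_now <- max(sc[1, ]) >= settings$early_stop_r2
      g <- 0
      while (!stop_now && g < settings$generations) {
        g <- g + 1
        elite <- pop[[which.max(sc[2, ])]]
        tournament <- function() {
          idx <- sample.int(length(pop), settings$tournament_size)
          pop[[idx[which.max(sc[2, idx])]]]
        }
        newpop <- vector("list", settings$population)
        newpop[[1]] <- elite
        for (i in 2:settings$population) {
          u <- runif(1)
          parent <- tournament()
          child <-
            if (u < settings$p_crossover) sr_crossover(parent, tournament())
            else if (u < settings$p_crossover + settings$p_mutation)
              sr_mutate(parent, p, settings$const_range)
            else parent
          if (sr_node_count(child) > settings$max_nodes) child <- parent
          newpop[[i]] <- child
        }
        pop <- newpop
        sc <- evaluate(pop)
        for (i in seq_along(pop)) consider(pop[[i]], sc[1, i])
        stop_now <- max(sc[1, ]) >= settings$early_stop_r2
      }
    }
    archive <- archive[order(as.integer(names(archive)))]
    records <- lapply(archive, function(a) {
      list(expression = sr_deparse(a$tree, fids), tree = a$tree,
           complexity = a$complexity, r2_train = a$r2_train,
           variables = fids[sr_tree_vars(a$tree)])
    })
    structure(list(archive = unname(records), settings = settings,
                   seed = seed, feature_ids = fids),
              class = "sr_run")
  })
}

#' @export
print.sr_run <- function(x, ...) {
  best <- which.max(vapply(x$archive, `[[`, 0, "r2_train"))
  cat(sprintf("sr_run: %d archived expressions; best r2 = %.3f: %s\n",
              length(x$archive), x$archive[[best]]$r2_train,
              x$archive[[best]]$expression))
  invisible(x)
}

qualifying_models <- function(run, r2_min, complexity_max) {
  Filter(function(a) a$r2_train >= r2_min && a$complexity <= complexity_max,
         run$archive)
}

#' Variable presence among top-performing SR models
#'
#' The qualifying set is every archived expression with training R2 at
#' least `r2_min` and complexity (node count) at most `complexity_max`;
#' presence of a feature is the fraction of qualifying models whose tree
#' contains it. An empty qualifying set yields all-zero presences with a
#' warning.
#'
#' @param run an `sr_run` from [sr_fit()].
#' @param r2_min training-R2 cutoff (default 0.90).
#' @param complexity_max node-count ceiling (default 300).
#' @return named numeric vector of presence fractions in \[0, 1\].
#' @export
variable_presence <- function(run, r2_min = 0.90, complexity_max = 300) {
  stopifnot(inherits(run, "sr_run"))
  out <- setNames(numeric(length(run$feature_ids)), run$feature_ids)
  qual <- qualifying_models(run, r2_min, complexity_max)
  if (length(qual) == 0) {
    warning("no archived SR model qualifies; all presences are 0")
    return(out)
  }
  for (a in qual) out[a$variables] <- out[a$variables] + 1
  out / length(qual)
}

#' Features important to the SR family
#'
#' Features present in at least `presence_min` of the qualifying SR models
#' (inclusive threshold).
#'
#' @inheritParams variable_presence
#' @param presence_min presence cutoff (default 0.10).
#' @return character vector of feature ids.
#' @export
sr_important_features <- function(run, presence_min = 0.10, r2_min = 0.90,
                                  complexity_max = 300) {
  pres <- suppressWarnings(variable_presence(run, r2_min, complexity_max))
  names(pres)[pres >= presence_min]
}

# ---- LOO evaluation of the best qualifying expression ---------------------

# split a tree into top-level additive terms with signs
sr_terms <- function(tree, sign = 1) {
  if (!is.null(tree$op) && tree$op %in% c("+", "-")) {
    s2 <- if (tree$op == "-") -sign else sign
    return(c(sr_terms(tree$args[[1]], sign), sr_terms(tree$args[[2]], s2)))
  }
  list(list(tree = tree, sign = sign))
}

#' Leave-one-out R2 of the best qualifying SR expression
#'
#' Freezes the structure of the best qualifying expression (highest training
#' R2, ties to lowest complexity) and, per leave-one-out fold, re-optimizes
#' its linear coefficients by least squares on the basis defined by the
#' tree's top-level additive terms, then pools predictions into an R2.
#'
#' @inheritParams variable_presence
#' @param X line x feature matrix (as passed to [sr_fit()]).
#' @param y a `composite_score` or named numeric vector.
#' @return list with `loo_r2`, `expression` and `variables`.
#' @export
sr_loo_r2 <- function(run, X, y, r2_min = 0.90, complexity_max = 300) {
  stopifnot(inherits(run, "sr_run"))
  X <- as.matrix(X)
  y <- score_vector(y, rownames(X))
  qual <- qualifying_models(run, r2_min, complexity_max)
  abort_if(length(qual) == 0, "no qualifying SR expression to evaluate")
  r2s <- vapply(qual, `[[`, 0, "r2_train")
  cxs <- vapply(qual, `[[`, 0, "complexity")
  best <- qual[[order(-r2s, cxs)[1]]]
  terms <- sr_terms(best$tree)
  basis <- vapply(terms, function(tm) tm$sign * sr_eval(tm$tree, X),
                  numeric(nrow(X)))
  basis <- matrix(basis, nrow = nrow(X))
  keep <- apply(basis, 2, function(col) sd(col) > 0)
  B <- cbind(1, basis[, keep, drop = FALSE])
  n <- nrow(X)
  yhat <- numeric(n)
  for (i in seq_len(n)) {
    co <- stats::lm.fit(B[-i, , drop = FALSE], y[-i])$coefficients
    co[is.na(co)] <- 0
    yhat[i] <- sum(B[i, ] * co)
  }
  list(loo_r2 = r_squared(y, yhat), expression = best$expression,
       variables = best$variables)
}
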