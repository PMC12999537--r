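# ---- draw unpacking -------------------------------------------------------

# index map from stored draw columns to structured parameter arrays;
# bracket indices are parsed once here, not per draw
draw_index_map <- function(fit) {
  nm <- colnames(fit$draws)
  I <- length(fit$items); D <- fit$wa$D; K1 <- fit$wa$K1
  grab <- function(pattern) {
    idx <- grep(pattern, nm)
    if (!length(idx)) {
      return(list(col = integer(), ij = matrix(0L, 0, 2)))
    }
    inner <- gsub("^[^\\[]+\\[|\\]$", "", nm[idx])
    parts <- strsplit(inner, ",", fixed = TRUE)
    ij <- matrix(0L, length(idx), 2)
    for (j in seq_along(parts)) {
      v <- as.integer(parts[[j]])
      ij[j, seq_along(v)] <- v
    }
    list(col = idx, ij = ij)
  }
  scalar <- function(name) {
    j <- match(name, nm)
    if (is.na(j)) integer() else j
  }
  list(I = I, D = D, K1 = K1,
       alpha_s = grab("^alpha_s\\["), alpha_f = grab("^alpha_f\\["),
       gamma_s = grab("^gamma_s\\["), gamma_sf = grab("^gamma_sf\\["),
       gamma_f = grab("^gamma_f\\["), beta = grab("^beta\\["),
       delta_s = grab("^delta_s\\["), delta_f = grab("^delta_f\\["),
       pi = grab("^pi\\["),
       nu_phi = scalar("nu_phi"), nu_psi = scalar("nu_psi"),
       lambda = scalar("lambda"),
       sigma_s = scalar("sigma_s"), sigma_sf = scalar("sigma_sf"),
       sigma_f = scalar("sigma_f"))
}

fill_vec <- function(target, d, gr) {
  if (length(gr$col)) target[gr$ij[, 1]] <- d[gr$col]
  target
}
fill_mat <- function(target, d, gr, col_offset = 0L) {
  if (length(gr$col)) {
    target[cbind(gr$ij[, 1], gr$ij[, 2] + col_offset)] <- d[gr$col]
  }
  target
}

unpack_draw <- function(fit, s, map = draw_index_map(fit)) {
  d <- fit$draws[s, ]
  I <- map$I; D <- map$D; K1 <- map$K1
  aS <- fill_mat(matrix(0, I, D), d, map$alpha_s)
  aF <- fill_vec(numeric(I), d, map$alpha_f)
  # stored gamma/beta names index category k (1..K) / class c (1, 2)
  gmat2 <- function(gr) fill_mat(matrix(0, I, K1), d, gr, col_offset = 1L)
  beta <- fill_mat(matrix(0, I, 3), d, map$beta, col_offset = 1L)
  dS <- fill_vec(numeric(I), d, map$delta_s)
  dF <- fill_vec(numeric(I), d, map$delta_f)
  pick <- function(j, default) if (length(j)) unname(d[j]) else default
  globals <- c(pick(map$nu_phi, 0), pick(map$nu_psi, 0),
               pick(map$lambda, 0), pick(map$sigma_s, 1),
               pick(map$sigma_sf, 1), pick(map$sigma_f, 1))
  lpi <- rep(log(1 / 3), 3)
  if (length(map$pi$col)) lpi <- log(pmax(d[map$pi$col], 1e-300))
  persons <- fit$person_draws[s, , , drop = TRUE]
  if (is.null(dim(persons))) persons <- matrix(persons, ncol = fit$config$P)
  list(aS = aS, aF = aF, gS = gmat2(map$gamma_s), gSF = gmat2(map$gamma_sf),
       gF = gmat2(map$gamma_f), beta = beta, dS = dS, dF = dF,
       globals = unname(globals), persons = persons, lpi = unname(lpi))
}

# per-cell per-class log terms for one posterior draw
draw_cell_terms <- function(fit, s, map = draw_index_map(fit)) {
  u <- unpack_draw(fit, s, map)
  cfg <- fit$config
  cell_terms_cpp(fit$y,
                 if (is.null(fit$logt)) matrix(0, nrow(fit$y), ncol(fit$y))
                 else fit$logt,
                 fit$wa$ws, fit$wa$wf,
                 cfg, u$aS, u$aF, u$gS, u$gSF, u$gF, u$beta, u$dS, u$dF,
                 u$globals, u$persons, u$lpi)
}

draw_subsample <- function(fit, n_draws) {
  S <- nrow(fit$draws)
  if (is.null(n_draws) || n_draws >= S) return(seq_len(S))
  round(seq(1, S, length.out = n_draws))
}

# ---- class probabilities --------------------------------------------------

#' Posterior class probabilities per person-item cell
#'
#' Two flavors are available. The structural mode plugs each posterior draw
#' of the latent response model parameters (strategy inclination scores,
#' slope, item-class intercepts) into the class-membership softmax and
#' averages over draws; it reflects the model-implied mixing proportions.
#' The conditional mode additionally conditions on the observed response
#' and response time of each cell (normalized mixture summands,
#' i.e. responsibilities), matching what sampling the classes within the
#' Gibbs scheme would imply.
#'
#' @param fit A mixture-model `"faking_fit"` (person-by-item or person
#'   mixture).
#' @param mode `"conditional"` or `"structural"`.
#' @param n_draws Number of (evenly thinned) posterior draws to average
#'   over.
#' @return Tibble with `person_id`, `item_id`, `class` (0/1/2),
#'   `probability`; rows for each cell sum to 1.
#' @export
class_probability_table <- function(fit,
                                    mode = c("conditional", "structural"),
                                    n_draws = 200) {
  mode <- match.arg(mode)
  if (fit$config$mixture == 0) {
    stop("Class probabilities are undefined for non-mixture models.")
  }
  map <- draw_index_map(fit)
  ss <- draw_subsample(fit, n_draws)
  N <- nrow(fit$y); I <- ncol(fit$y)
  acc <- array(0, c(N, I, 3))
  for (s in ss) {
    terms <- draw_cell_terms(fit, s, map)
    lp <- terms$cls
    if (mode == "conditional") {
      lp <- lp + terms$resp
      if (fit$config$include_rt) lp <- lp + terms$rt
      if (fit$config$mixture == 1) {
        # person-level membership: condition on the person's whole record
        lp <- aperm(apply(lp, c(1, 3), sum) %o% rep(1, I), c(1, 3, 2))
      }
    }
    m <- pmax(lp[, , 1], pmax(lp[, , 2], lp[, , 3]))
    e <- exp(lp - as.vector(m))
    tot <- e[, , 1] + e[, , 2] + e[, , 3]
    acc <- acc + e / as.vector(tot)
  }
  acc <- acc / length(ss)
  out <- tidyr::expand_grid(person_id = fit$persons, item_id = fit$items,
                            class = 0:2)
  idx <- cbind(rep(rep(seq_len(N), each = I), each = 3)[seq_len(N * I * 3)],
               rep(rep(seq_len(I), times = N), each = 3),
               rep(1:3, times = N * I))
  out$probability <- acc[idx]
  attr(out, "mode") <- mode
  class(out) <- c("class_probability_table", class(out))
  out
}

#' Class proportion estimates with credible intervals
#'
#' Draw-wise mean class probabilities across persons (per item or across
#' all items), summarized by their posterior mean and central 95% interval.
#'
#' @inheritParams class_probability_table
#' @param by `"overall"` or `"item"`.
#' @return Tibble with `class`, proportion `estimate`, `conf.low`,
#'   `conf.high` (and `item_id` when `by = "item"`).
#' @export
class_proportions <- function(fit, mode = c("structural", "conditional"),
                              by = c("overall", "item"), n_draws = 200) {
  mode <- match.arg(mode); by <- match.arg(by)
  if (fit$config$mixture == 0) {
    stop("Class proportions are undefined for non-mixture models.")
  }
  map <- draw_index_map(fit)
  ss <- draw_subsample(fit, n_draws)
  N <- nrow(fit$y); I <- ncol(fit$y)
  res <- vector("list", length(ss))
  for (j in seq_along(ss)) {
    terms <- draw_cell_terms(fit, ss[j], map)
    lp <- terms$cls
    if (mode == "conditional") {
      lp <- lp + terms$resp
      if (fit$config$include_rt) lp <- lp + terms$rt
    }
    m <- pmax(lp[, , 1], pmax(lp[, , 2], lp[, , 3]))
    e <- exp(lp - as.vector(m))
    tot <- e[, , 1] + e[, , 2] + e[, , 3]
    p <- e / as.vector(tot)
    res[[j]] <- if (by == "overall") apply(p, 3, mean)
                else apply(p, c(2, 3), mean)
  }
  if (by == "overall") {
    mat <- do.call(rbind, res)
    tibble::tibble(class = 0:2,
                   estimate = colMeans(mat),
                   conf.low = apply(mat, 2, quantile, 0.025),
                   conf.high = apply(mat, 2, quantile, 0.975))
  } else {
    arr <- simplify2array(res)   # I x 3 x draws
    tibble::tibble(
      item_id = rep(fit$items, 3),
      class = rep(0:2, each = I),
      estimate = as.vector(apply(arr, c(1, 2), mean)),
      conf.low = as.vector(apply(arr, c(1, 2), quantile, 0.025)),
      conf.high = as.vector(apply(arr, c(1, 2), quantile, 0.975)))
  }
}

#' Modal class assignment per person-item cell
#'
#' Assigns each cell to the class with the highest posterior class
#' probability; exact ties break toward the lower class index (the less
#' pronounced self-presentation strategy).
#'
#' @param table A [class_probability_table()].
#' @return Tibble with `person_id`, `item_id`, `class`.
#' @export
modal_assignment <- function(table) {
  table |>
    dplyr::group_by(.data$person_id, .data$item_id) |>
    dplyr::summarise(
      class = .data$class[which.max(.data$probability)],
      .groups = "drop")
}

#' Strategy-use consistency across items
#'
#' Summarizes, per person, how many distinct strategies the modal
#' assignments use and which combination.
#'
#' @param assignments Output of [modal_assignment()].
#' @return List with `per_person` (person_id, n_classes, pattern) and
#'   `summary` (pattern counts).
#' @export
strategy_consistency <- function(assignments) {
  lab <- c("S-only", "S&F", "F-only")
  per_person <- assignments |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(
      n_classes = dplyr::n_distinct(.data$class),
      pattern = paste(lab[sort(unique(.data$class)) + 1], collapse = "/"),
      .groups = "drop")
  summary <- per_person |>
    dplyr::count(.data$n_classes, .data$pattern, name = "n_persons") |>
    dplyr::arrange(.data$n_classes, .data$pattern)
  list(per_person = per_person, summary = summary)
}

#' Item-level hit rate of class assignments
#'
#' Percentage of person-item cells whose modal class assignment matches the
#' generating class, pooled over all cells.
#'
#' @param assignments Output of [modal_assignment()].
#' @param data Simulated `"assessment_data"` carrying `true_class`.
#' @return Percentage in `[0, 100]`.
#' @export
hit_rate <- function(assignments, data) {
  if (!"true_class" %in% names(data) || anyNA(data$true_class)) {
    stop("Ground-truth classes are required to compute a hit rate.")
  }
  joined <- dplyr::inner_join(
    assignments, data[c("person_id", "item_id", "true_class")],
    by = c("person_id", "item_id"))
  if (nrow(joined) != nrow(assignments)) {
    stop("Assignments and data do not cover the same cells.")
  }
  100 * mean(joined$class == joined$true_class)
}

#' Bias, RMSE and recovery correlations of parameter estimates
#'
#' @param df Tibble with columns `family` (parameter family label),
#'   `truth`, `estimate`, and optionally `replication`.
#' @return Tibble per family: `bias` (mean estimate minus truth), `rmse`,
#'   and `correlation` (mean across replications of the truth-estimate
#'   correlation, aggregated via Fisher's z; `NA` for families with fewer
#'   than 3 values per replication).
#' @export
recovery_metrics <- function(df) {
  stopifnot(all(c("family", "truth", "estimate") %in% names(df)))
  if (nrow(df) == 0) stop("Empty recovery table.")
  if (!"replication" %in% names(df)) df$replication <- 1L
  if (anyNA(df$truth) || anyNA(df$estimate)) {
    stop("Estimate/truth values must be complete.")
  }
  corr_fun <- function(est, tru) {
    if (length(est) < 3 || sd(tru) == 0 || sd(est) == 0) return(NA_real_)
    r <- cor(est, tru)
    # guard atanh at |r| = 1
    atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  }
  df |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      n = dplyr::n(),
      bias = mean(.data$estimate - .data$truth),
      rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
      correlation = tanh(mean(
        vapply(split(seq_len(dplyr::n()), .data$replication),
               function(ix) corr_fun(.data$estimate[ix], .data$truth[ix]),
               numeric(1)), na.rm = TRUE)),
      .groups = "drop")
}
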