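## Dataset and checkpoint serialisation. Everything is plain text: CSV for
## trajectories, JSON for model checkpoints, reports and manifests.

#' Read a trajectory CSV into a transition dataset
#'
#' Expected header: \code{t, x0..x\{p-1\}, trajectory_id}. Transition pairs
#' are formed from consecutive rows (ordered by \code{t}) within each
#' \code{trajectory_id}; no pair crosses a trajectory boundary.
#'
#' @param path CSV file path.
#' @return a \code{\link{transition_dataset}}.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, data.table = TRUE)
  if (nrow(dt) == 0L) stop("empty trajectory file: ", path)
  cols <- names(dt)
  xcols <- grep("^x[0-9]+$", cols, value = TRUE)
  if (!all(c("t", "trajectory_id") %in% cols) || length(xcols) == 0L)
    stop("header must be t, x0..x{p-1}, trajectory_id; got: ",
         paste(cols, collapse = ", "))
  xcols <- xcols[order(as.integer(sub("^x", "", xcols)))]
  for (cc in c("t", xcols)) {
    v <- dt[[cc]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
      stop("non-numeric values in column '", cc, "' at data row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  data.table::setorderv(dt, c("trajectory_id", "t"))
  X <- as.matrix(dt[, xcols, with = FALSE])
  id <- dt[["trajectory_id"]]
  keep <- which(id[-length(id)] == id[-1L])
  if (length(keep) == 0L) stop("no consecutive pairs within any trajectory")
  transition_dataset(X[keep, , drop = FALSE], X[keep + 1L, , drop = FALSE],
                     system_name = paste0("csv:", basename(path)))
}

#' Write a transition dataset as a trajectory CSV
#'
#' Each transition pair becomes a two-row trajectory (t = 0, 1) so that
#' \code{\link{read_trajectories}} recovers exactly the same pairs.
#'
#' @param data a \code{\link{transition_dataset}}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_trajectories <- function(data, path) {
  stopifnot(inherits(data, "transition_dataset"))
  n <- data$n; p <- data$p
  X <- matrix(NA_real_, 2L * n, p)
  X[seq(1L, 2L * n, by = 2L), ] <- data$x_t
  X[seq(2L, 2L * n, by = 2L), ] <- data$x_next
  out <- data.table::as.data.table(X)
  data.table::setnames(out, paste0("x", seq_len(p) - 1L))
  out <- cbind(data.table::data.table(t = rep(c(0L, 1L), n)), out,
               data.table::data.table(trajectory_id = rep(seq_len(n),
                                                          each = 2L)))
  data.table::fwrite(out, path)
  invisible(path)
}

## ---- model checkpoints -----------------------------------------------------

mlp_to_list <- function(net) {
  list(sizes = net$sizes,
       W = lapply(net$W, function(w) unname(as.matrix(w))),
       b = lapply(net$b, as.numeric))
}

## JSON stores matrices as arrays of rows (jsonlite's row-major layout).
mlp_from_list <- function(lst) {
  sizes <- as.integer(unlist(lst$sizes))
  W <- vector("list", length(lst$W))
  for (l in seq_along(lst$W)) {
    W[[l]] <- matrix(as.numeric(unlist(lst$W[[l]])),
                     nrow = sizes[l], ncol = sizes[l + 1L], byrow = TRUE)
  }
  b <- lapply(lst$b, function(v) as.numeric(unlist(v)))
  structure(list(W = W, b = b, sizes = sizes), class = "nisr_mlp")
}

#' Save a model checkpoint
#'
#' Writes the full squeezer (bijector and dynamics parameters, q, noise
#' scales, noise family) to a single JSON file at full double precision.
#'
#' @param model a \code{nis_model}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
nis_save <- function(model, path) {
  stopifnot(inherits(model, "nis_model"))
  blocks <- lapply(model$bijector$blocks, function(blk)
    list(idx_a = blk$idx_a, idx_b = blk$idx_b,
         s_net = mlp_to_list(blk$s_net), t_net = mlp_to_list(blk$t_net)))
  payload <- list(
    format = "nisr-checkpoint-1",
    p = model$p, q = model$q,
    bijector = list(p = model$bijector$p,
                    n_blocks = model$bijector$n_blocks,
                    hidden = model$bijector$hidden,
                    s_cap = model$bijector$s_cap,
                    blocks = blocks),
    dyn_net = mlp_to_list(model$dyn_net),
    sigma = as.numeric(model$sigma),
    micro_sigma = as.numeric(model$micro_sigma),
    code_center = as.numeric(model$code_center),
    code_scale = as.numeric(model$code_scale),
    noise_family = model$noise_family,
    trained = model$trained)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path JSON file written by \code{\link{nis_save}}.
#' @return a \code{nis_model}.
#' @export
nis_load <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(js$format, "nisr-checkpoint-1"))
    stop("not a nisr checkpoint: ", path)
  bj <- js$bijector
  blocks <- lapply(js$bijector$blocks, function(blk)
    list(idx_a = as.integer(unlist(blk$idx_a)),
         idx_b = as.integer(unlist(blk$idx_b)),
         s_net = mlp_from_list(blk$s_net),
         t_net = mlp_from_list(blk$t_net)))
  bijector <- structure(list(p = as.integer(bj$p),
                             n_blocks = as.integer(bj$n_blocks),
                             hidden = as.integer(bj$hidden),
                             s_cap = as.numeric(bj$s_cap), blocks = blocks),
                        class = "nisr_bijector")
  structure(list(p = as.integer(js$p), q = as.integer(js$q),
                 bijector = bijector,
                 dyn_net = mlp_from_list(js$dyn_net),
                 sigma = as.numeric(unlist(js$sigma)),
                 micro_sigma = as.numeric(unlist(js$micro_sigma)),
                 code_center = if (is.null(js$code_center))
                   rep(0, as.integer(js$q))
                   else as.numeric(unlist(js$code_center)),
                 code_scale = if (is.null(js$code_scale))
                   rep(1, as.integer(js$q))
                   else as.numeric(unlist(js$code_scale)),
                 noise_family = as.character(js$noise_family),
                 trained = isTRUE(js$trained)),
            class = "nis_model")
}
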