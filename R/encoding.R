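# Feature encoding: claim events -> fixed-length numeric vectors x_t in R^d,
# padded sequence batches for sequence models, event-view matrices for
# MLP/logistic regression, and inverse-frequency class weights.
#
# Vocabularies and numeric statistics are always learned from the training
# fold only; unseen categories map to an explicit UNK slot so the dimension d
# never changes at transform time.

UNK <- "__UNK__"

CAT_SINGLE <- c("primary_dx", "sex", "pay_source")
CAT_MULTI <- c("secondary_dx", "procedures", "comorbidities")
NUMERIC_FIELDS <- c("age_years", "length_of_stay", "event_index")

flat_events <- function(timelines) {
  ev <- do.call(rbind, lapply(timelines, function(tl) tl$events))
  ev$event_index <- unlist(lapply(timelines, function(tl) seq_len(tl$length)))
  ev
}

split_tokens <- function(x) strsplit(x, ";", fixed = TRUE)

num_stats <- function(x, name) {
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    message(sprintf("numeric field `%s` is constant in training data; using SD = 1", name))
    s <- 1
  }
  c(mean = m, sd = s)
}

#' Fit a feature schema on training timelines
#'
#' Learns categorical vocabularies (lexicographically sorted, plus an UNK
#' slot per block) and numeric mean/SD statistics from the training fold
#' only. Also records statistics for the optional timeline-summary features
#' (prior admission count, prior HF count) used by event-view models.
#'
#' @param timelines training `timeline_set`.
#' @return a `feature_schema` with total per-event dimension `d`.
#' @export
fit_schema <- function(timelines) {
  if (!length(timelines)) stopf("cannot fit a schema on an empty training set")
  ev <- flat_events(timelines)
  vocab <- list()
  for (col in CAT_SINGLE)
    vocab[[col]] <- c(sort(unique(ev[[col]])), UNK)
  for (col in CAT_MULTI) {
    toks <- unlist(split_tokens(ev[[col]]))
    toks <- toks[nzchar(toks)]
    vocab[[col]] <- c(sort(unique(toks)), UNK)
  }
  numeric <- lapply(stats::setNames(NUMERIC_FIELDS, NUMERIC_FIELDS),
                    function(col) num_stats(ev[[col]], col))
  prior_events <- ev$event_index - 1
  prior_hf <- unlist(lapply(timelines, function(tl)
    cumsum(c(0L, tl$is_hf))[seq_len(tl$length)]))
  summary_stats <- list(prior_events = num_stats(prior_events, "prior_events"),
                        prior_hf = num_stats(prior_hf, "prior_hf"))
  blocks <- c(CAT_SINGLE, CAT_MULTI)
  sizes <- vapply(vocab[blocks], length, integer(1))
  offsets <- cumsum(c(0L, sizes))[seq_along(blocks)]
  names(offsets) <- blocks
  d <- sum(sizes) + length(NUMERIC_FIELDS)
  feature_names <- c(
    unlist(lapply(blocks, function(b) paste0(b, "=", vocab[[b]]))),
    NUMERIC_FIELDS
  )
  structure(list(
    vocab = vocab, numeric = numeric, summary_stats = summary_stats,
    offsets = offsets, d = d, feature_names = feature_names
  ), class = "feature_schema")
}

# Encode a flat events data.frame (with an `event_index` column) into an
# n x d matrix. Vectorized over rows; unseen categories land in UNK slots.
encode_events_matrix <- function(ev, schema) {
  n <- nrow(ev)
  X <- matrix(0, n, schema$d)
  colnames(X) <- schema$feature_names
  for (col in CAT_SINGLE) {
    voc <- schema$vocab[[col]]
    idx <- match(ev[[col]], voc)
    idx[is.na(idx)] <- length(voc)
    X[cbind(seq_len(n), schema$offsets[[col]] + idx)] <- 1
  }
  for (col in CAT_MULTI) {
    voc <- schema$vocab[[col]]
    toks <- split_tokens(ev[[col]])
    lens <- lengths(toks)
    if (sum(lens)) {
      rows <- rep.int(seq_len(n), lens)
      tk <- unlist(toks)
      keep <- nzchar(tk)
      idx <- match(tk[keep], voc)
      idx[is.na(idx)] <- length(voc)
      X[cbind(rows[keep], schema$offsets[[col]] + idx)] <- 1
    }
  }
  off <- sum(vapply(schema$vocab, length, integer(1)))
  for (j in seq_along(NUMERIC_FIELDS)) {
    st <- schema$numeric[[NUMERIC_FIELDS[j]]]
    X[, off + j] <- (ev[[NUMERIC_FIELDS[j]]] - st[["mean"]]) / st[["sd"]]
  }
  X
}

#' Encode one timeline as a padded sequence
#'
#' Timelines longer than `t_max` keep the most recent `t_max` events (the
#' prediction target is the last HF event); `event_index` retains the
#' position in the full timeline. Rows beyond the sequence length are zero
#' and masked.
#'
#' @param timeline a `patient_timeline` whose last event is HF.
#' @param schema a fitted [fit_schema()].
#' @param t_max padded length (>= 1).
#' @return list with `X` (`t_max x d`), `mask`, `y`, `hf`, `len`,
#'   `last_hf_index`.
#' @export
encode_timeline <- function(timeline, schema, t_max) {
  stopifnot(t_max >= 1L)
  if (!timeline$is_hf[timeline$last_hf_index])
    stopf("timeline %s: last event is not an HF event", timeline$patient_id)
  b <- encode_batch(structure(list(timeline), class = "timeline_set"),
                    schema, t_max)
  X <- matrix(b$X[1, , ], nrow = b$t_max, ncol = b$d,
              dimnames = list(NULL, schema$feature_names))
  list(X = X, mask = b$mask[1, ], y = b$y[1, ],
       hf = b$hf[1, ], len = b$len[1], last_hf_index = b$len[1])
}

#' Encode a set of timelines as batched arrays
#'
#' @param timelines a `timeline_set`.
#' @param schema a fitted [fit_schema()].
#' @param t_max padded length.
#' @param split optional split tag ("train"/"valid"/"test") carried on the
#'   batch; [fit_model()] refuses to train on a batch tagged "test".
#' @return a `seq_batch`: `X` (`n x t_max x d` array), `mask`, `y`, `hf`
#'   (`n x t_max` matrices), `len`, `n`, `d`, `t_max`.
#' @export
encode_batch <- function(timelines, schema, t_max, split = NULL) {
  stopifnot(inherits(schema, "feature_schema"), t_max >= 1L)
  n <- length(timelines)
  if (!n) stopf("cannot encode an empty timeline set")
  bad <- which(!vapply(timelines, function(tl) tl$is_hf[tl$last_hf_index],
                       logical(1)))
  if (length(bad))
    stopf("timeline(s) whose last event is not HF: %s",
          paste(utils::head(bad, 5L), collapse = ", "))
  t_max <- as.integer(t_max)
  keep_idx <- lapply(timelines, function(tl) {
    T_i <- tl$length
    seq.int(max(1L, T_i - t_max + 1L), T_i)
  })
  lens <- lengths(keep_idx)
  ev <- do.call(rbind, Map(function(tl, idx) tl$events[idx, , drop = FALSE],
                           timelines, keep_idx))
  ev$event_index <- unlist(keep_idx)
  V <- encode_events_matrix(ev, schema)
  tl_id <- rep.int(seq_len(n), lens)
  step <- unlist(lapply(lens, seq_len))
  Xmat <- matrix(0, n * t_max, schema$d)
  Xmat[tl_id + (step - 1L) * n, ] <- V
  dim(Xmat) <- c(n, t_max, schema$d)
  fill <- function(get) {
    M <- matrix(0L, n, t_max)
    M[cbind(tl_id, step)] <- unlist(Map(get, timelines, keep_idx))
    M
  }
  mask <- matrix(FALSE, n, t_max)
  mask[cbind(tl_id, step)] <- TRUE
  b <- list(
    X = Xmat, mask = mask,
    y = fill(function(tl, idx) tl$labels[idx]),
    hf = fill(function(tl, idx) as.integer(tl$is_hf[idx])),
    len = as.integer(lens), n = n, d = schema$d, t_max = t_max
  )
  class(b) <- "seq_batch"
  attr(b, "split") <- split
  b
}

#' Event-view feature matrix (last HF event per patient)
#'
#' Used by the index-event classification models (MLP, logistic regression).
#' With `summary_features = TRUE`, two standardized timeline-summary columns
#' (prior admission count, prior HF count) are appended; this augmentation is
#' intended for event-view models only.
#'
#' @param timelines a `timeline_set`.
#' @param schema a fitted [fit_schema()].
#' @param summary_features append timeline-summary features?
#' @return list with `X` (`n x d` or `n x (d+2)` matrix) and `y` (labels of
#'   the last HF events).
#' @export
event_view_features <- function(timelines, schema, summary_features = FALSE) {
  stopifnot(inherits(schema, "feature_schema"))
  ev <- do.call(rbind, lapply(timelines, function(tl)
    tl$events[tl$last_hf_index, , drop = FALSE]))
  ev$event_index <- vapply(timelines, function(tl) tl$last_hf_index,
                           integer(1))
  X <- encode_events_matrix(ev, schema)
  if (summary_features) {
    pe <- ev$event_index - 1
    ph <- vapply(timelines, function(tl)
      sum(tl$is_hf[seq_len(tl$last_hf_index - 1L)]), integer(1))
    st <- schema$summary_stats
    X <- cbind(X,
               prior_events = (pe - st$prior_events[["mean"]]) / st$prior_events[["sd"]],
               prior_hf = (ph - st$prior_hf[["mean"]]) / st$prior_hf[["sd"]])
  }
  list(X = X, y = last_event_labels(timelines))
}

#' Default padded length: 95th percentile of training lengths, capped at 20
#' @param timelines training `timeline_set`.
#' @param cap maximum padded length.
#' @return integer `t_max`.
#' @export
default_t_max <- function(timelines, cap = 20L) {
  q <- stats::quantile(timeline_lengths(timelines), 0.95, names = FALSE,
                       type = 1)
  max(1L, min(as.integer(ceiling(q)), as.integer(cap)))
}

#' Inverse-frequency class weights
#'
#' `w_c = N / (|V_label| * N_c)`, so the weighted frequency mean over the
#' training labels equals 1.
#'
#' @param labels training labels in \{0, 1\}.
#' @return named numeric vector `c("0" = w_0, "1" = w_1)`.
#' @export
class_weights <- function(labels) {
  n <- length(labels)
  n1 <- sum(labels == 1L)
  n0 <- n - n1
  if (n0 == 0L || n1 == 0L)
    stopf("both classes must be present to compute class weights")
  c("0" = n / (2 * n0), "1" = n / (2 * n1))
}

#' Serialize / restore a feature schema as JSON
#' @param schema a `feature_schema`.
#' @param path file path.
#' @return `read_schema()` returns the `feature_schema`.
#' @export
write_schema <- function(schema, path) {
  out <- unclass(schema)
  out$numeric <- lapply(out$numeric, as.list)
  out$summary_stats <- lapply(out$summary_stats, as.list)
  out$offsets <- as.list(out$offsets)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$numeric <- lapply(raw$numeric, unlist)
  raw$summary_stats <- lapply(raw$summary_stats, unlist)
  raw$offsets <- unlist(raw$offsets)
  structure(raw, class = "feature_schema")
}
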