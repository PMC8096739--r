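# Experimental designs: stimulus sets, serially balanced carry-over
# sequences, and per-run trial timelines for the three imagery/perception
# experiments.

experiment_layout <- function(experiment) {
  switch(as.character(experiment),
    "1" = list(n_runs = 5L, per_cond = 5L, n_null = 5L, n_question = 9L),
    "2" = list(n_runs = 3L, per_cond = 6L, n_null = 12L, n_question = 6L),
    "3" = list(n_runs = 5L, per_cond = 5L, n_null = 5L, n_question = 9L),
    stop("unknown experiment id: ", experiment, call. = FALSE)
  )
}

.exp1_items <- function() {
  buildings <- c("Department of Literature", "Department of Mathematics",
                 "Department of Chemistry", "Orthopedics Clinic",
                 "Institute of Hygiene", "Chapel",
                 "Department of Political Science", "Department of Law")
  cities <- c("Bolzano", "Trieste", "Lecce", "Foggia",
              "Salerno", "Frosinone", "Alessandria", "Cuneo")
  hours <- c("01:00", "02:00", "04:00", "05:00",
             "07:00", "08:00", "10:00", "11:00")
  # Two items per quadrant per category. Hours follow the clock face and
  # cities follow Italian geography; the campus layout is not public, so
  # buildings get a two-per-quadrant assignment in listed order (override
  # via the `items` argument of make_stimulus_set() if a real layout is
  # available).
  quadrants <- rep(c("NE", "SE", "SW", "NW"), each = 2L)
  data.frame(
    label = c(buildings, cities, hours),
    category = rep(c("building", "city", "hour"), each = 8L),
    quadrant = rep(quadrants, times = 3L),
    stringsAsFactors = FALSE
  )
}

.exp3_items <- function() {
  buildings <- c("Department of Literature", "Orthopedics Clinic",
                 "Institute of Hygiene", "Chapel",
                 "Department of Mathematics", "Department of Law")
  faces <- paste("Famous face", 1:6)
  data.frame(
    label = c(buildings, faces),
    category = rep(c("building", "face"), each = 6L),
    quadrant = NA_character_,
    stringsAsFactors = FALSE
  )
}

slugify <- function(x) {
  x <- tolower(gsub("[^A-Za-z0-9]+", "_", x))
  gsub("^_|_$", "", x)
}

#' Build the condition set of one experiment
#'
#' Returns the full list of analysis conditions (item x domain) of the
#' requested experiment: Experiment 1 has 24 imagery-only conditions
#' (8 buildings, 8 cities on the map of Italy, 8 hours on the clock face,
#' two items per spatial quadrant per category); Experiment 2 crosses the
#' 8 buildings with imagery and perception (16 conditions); Experiment 3
#' crosses 6 buildings and 6 famous faces with both domains (24 conditions,
#' no quadrant factor in the analysis).
#'
#' @param experiment 1, 2 or 3.
#' @param items optional data.frame overriding the default item table; must
#'   have columns `label`, `category`, `quadrant` (NA allowed).
#' @return a data.frame with one row per condition and columns
#'   `condition_id`, `item_id`, `label`, `category`, `quadrant`, `domain`,
#'   `experiment`.
#' @examples
#' nrow(make_stimulus_set(1)) # 24
#' table(make_stimulus_set(2)$domain)
#' @export
make_stimulus_set <- function(experiment, items = NULL) {
  experiment <- as.integer(experiment)
  layout <- experiment_layout(experiment) # validates the id
  if (is.null(items)) {
    items <- switch(as.character(experiment),
      "1" = .exp1_items(),
      "2" = .exp1_items()[.exp1_items()$category == "building", ],
      "3" = .exp3_items())
  }
  stopifnot(all(c("label", "category", "quadrant") %in% names(items)))
  items$item_id <- paste0(substr(items$category, 1, 3), "_", slugify(items$label))
  domains <- if (experiment == 1L) "imagery" else c("imagery", "perception")
  out <- do.call(rbind, lapply(domains, function(d) {
    df <- items
    df$domain <- d
    df
  }))
  out$experiment <- experiment
  out$condition_id <- paste(out$domain, out$item_id, sep = ":")
  rownames(out) <- NULL
  out[, c("condition_id", "item_id", "label", "category",
          "quadrant", "domain", "experiment")]
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

# A circulant offset multiset yields a strongly connected digraph on
# Z/n iff its nonzero offsets and n are jointly coprime.
offsets_connected <- function(offsets, n) {
  nz <- offsets[offsets != 0L]
  if (length(nz) == 0L) return(n == 1L)
  Reduce(gcd2, c(nz, n)) == 1L
}

# Hierholzer's algorithm on an adjacency list whose edge order has already
# been randomized; returns a closed node walk (first == last) using every
# edge exactly once.
eulerian_circuit <- function(adj, start = 1L) {
  ptr <- rep(1L, length(adj))
  stack <- start
  path <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    if (ptr[v] <= length(adj[[v]])) {
      nxt <- adj[[v]][ptr[v]]
      ptr[v] <- ptr[v] + 1L
      stack <- c(stack, nxt)
    } else {
      path <- c(path, v)
      stack <- stack[-length(stack)]
    }
  }
  rev(path)
}

circulant_adjacency <- function(n, offsets) {
  lapply(seq_len(n), function(v) {
    tg <- ((v - 1L + offsets) %% n) + 1L
    if (length(tg) > 1L) sample(tg) else tg
  })
}

#' Serially balanced (carry-over) stimulus sequence
#'
#' Generates an ordered sequence of item indices in which every ordered
#' successor pair -- including self-successions -- occurs as equally often
#' as the sequence length allows (max - min pair count <= 1), the defining
#' property of a continuous carry-over design. Construction is an Eulerian
#' circuit: when `n_trials` is a multiple of `n_items` (or one more than a
#' multiple), the circuit is taken on an m-regular circulant sub-digraph of
#' the complete directed graph with self-loops, so that every item also
#' appears exactly `n_trials / n_items` times; otherwise the walk follows a
#' repeated Eulerian circuit on the full complete digraph, truncated to
#' length.
#'
#' @param n_items number of distinct items (>= 1).
#' @param n_trials sequence length (>= 1).
#' @param seed integer seed; the same seed gives the identical sequence.
#' @param offsets optional integer vector of circulant offsets in
#'   `0:(n_items-1)` to use (advanced; lets callers coordinate offsets
#'   across runs so a whole session covers all ordered pairs).
#' @return integer vector of length `n_trials` with values in `1:n_items`.
#' @examples
#' s <- carryover_sequence(3, 10, seed = 1)
#' table(paste(s[-10], s[-1])) # each of the 9 ordered pairs once
#' @export
carryover_sequence <- function(n_items, n_trials, seed = 1L, offsets = NULL) {
  n_items <- as.integer(n_items); n_trials <- as.integer(n_trials)
  stopifnot(n_items >= 1L, n_trials >= 1L)
  if (n_items == 1L) return(rep(1L, n_trials))
  with_seed(seed, {
    if (!is.null(offsets)) {
      offsets <- as.integer(offsets) %% n_items
      if (!offsets_connected(offsets, n_items))
        stop("supplied offsets do not yield a connected carry-over graph",
             call. = FALSE)
      m <- length(offsets)
      if (n_trials != m * n_items && n_trials != m * n_items + 1L)
        stop("with ", m, " offsets, n_trials must be ", m * n_items,
             " or ", m * n_items + 1L, call. = FALSE)
    } else if (n_trials %/% n_items >= 1L &&
               (n_trials %% n_items == 0L || (n_trials - 1L) %% n_items == 0L)) {
      m <- n_trials %/% n_items
      offsets <- draw_offsets(n_items, m)
    }
    if (!is.null(offsets)) {
      walk <- eulerian_circuit(circulant_adjacency(n_items, offsets),
                               start = sample.int(n_items, 1L))
      if (n_trials == length(walk)) walk else walk[seq_len(n_trials)]
    } else {
      # arbitrary length: repeat a full complete-digraph circuit
      walk <- eulerian_circuit(circulant_adjacency(n_items, 0:(n_items - 1L)),
                               start = sample.int(n_items, 1L))
      rep(walk[seq_len(n_items^2)], length.out = n_trials)
    }
  })
}

# Random multiset of m circulant offsets giving a connected graph. For
# m >= n all offsets are included floor(m/n) times plus a random remainder.
draw_offsets <- function(n, m) {
  full <- rep(0:(n - 1L), times = m %/% n)
  r <- m %% n
  if (r == 0L) {
    if (length(full) == 0L) stop("m must be >= 1", call. = FALSE)
    return(full)
  }
  for (i in 1:500) {
    extra <- sample(0:(n - 1L), r)
    off <- c(full, extra)
    if (offsets_connected(off, n)) return(off)
  }
  stop("failed to draw connected offsets", call. = FALSE) # unreachable in practice
}

# Partition circulant offsets across the runs of an experiment so the whole
# session approaches full ordered-pair coverage; each run's set must give a
# connected graph.
run_offsets <- function(n_items, n_runs, per_cond, seed) {
  with_seed(seed, {
    for (i in 1:500) {
      perm <- sample(0:(n_items - 1L))
      slots <- rep(perm, length.out = n_runs * per_cond)
      sets <- split(slots, rep(seq_len(n_runs), each = per_cond))
      if (all(vapply(sets, offsets_connected, TRUE, n = n_items)))
        return(unname(sets))
    }
  })
  stop("failed to partition offsets", call. = FALSE)
}

#' Build one run's trial timeline
#'
#' Assembles the ordered, timed trial list of one fMRI run: the
#' experimental trials follow a serially balanced carry-over sequence over
#' the experiment's conditions (each condition shown equally often per run:
#' 5x in Experiments 1 and 3, 6x in Experiment 2), and the run's null and
#' question trials are inserted at seeded random positions. Experimental
#' and null trials last 2 s and are followed by a 2 s fixation gap;
#' question trials last 4 s.
#'
#' @param experiment 1, 2 or 3.
#' @param run_id run index within the experiment (1..5, 1..3, 1..5).
#' @param seed integer seed for the whole experiment; run `run_id` is
#'   reproducible on its own because per-run substreams are derived with
#'   [child_seed()].
#' @param conditions optional condition table from [make_stimulus_set()].
#' @return a data.frame of class `trial_timeline` with columns `onset`,
#'   `duration`, `kind` (experimental/null/question), `condition_id`,
#'   `item_id`, `label`, `category`, `domain`, `quadrant`, and attributes
#'   `conditions`, `experiment`, `run_id`.
#' @export
build_trial_timeline <- function(experiment, run_id, seed = 1L,
                                 conditions = NULL) {
  experiment <- as.integer(experiment)
  layout <- experiment_layout(experiment)
  run_id <- as.integer(run_id)
  if (run_id < 1L || run_id > layout$n_runs)
    stop("run_id out of range: experiment ", experiment, " has ",
         layout$n_runs, " runs", call. = FALSE)
  if (is.null(conditions)) conditions <- make_stimulus_set(experiment)
  n <- nrow(conditions)
  offs <- run_offsets(n, layout$n_runs, layout$per_cond,
                      child_seed(seed, "offsets", experiment))[[run_id]]
  seq_cond <- carryover_sequence(n, layout$per_cond * n,
                                 seed = child_seed(seed, "seq", experiment, run_id),
                                 offsets = offs)
  n_extra <- layout$n_null + layout$n_question
  n_total <- length(seq_cond) + n_extra
  kinds <- rep("experimental", n_total)
  probe <- rep(NA_integer_, n_total)
  with_seed(child_seed(seed, "insert", experiment, run_id), {
    pos <- sample.int(n_total, n_extra)
    kinds[pos[seq_len(layout$n_null)]] <- "null"
    qpos <- pos[layout$n_null + seq_len(layout$n_question)]
    kinds[qpos] <- "question"
    probe[qpos] <- sample.int(n, layout$n_question, replace = TRUE)
  })
  cond_idx <- rep(NA_integer_, n_total)
  cond_idx[kinds == "experimental"] <- seq_cond
  duration <- ifelse(kinds == "question", 4, 2)
  gap <- ifelse(kinds == "question", 0, 2)
  onset <- cumsum(c(0, (duration + gap)[-n_total]))
  pick <- function(col) {
    out <- conditions[[col]][cond_idx]
    qi <- which(kinds == "question")
    if (col %in% c("item_id", "label")) out[qi] <- conditions[[col]][probe[qi]]
    out
  }
  tl <- data.frame(
    onset = onset, duration = duration, kind = kinds,
    condition_id = pick("condition_id"), item_id = pick("item_id"),
    label = pick("label"), category = pick("category"),
    domain = pick("domain"), quadrant = pick("quadrant"),
    stringsAsFactors = FALSE
  )
  attr(tl, "conditions") <- conditions
  attr(tl, "experiment") <- experiment
  attr(tl, "run_id") <- run_id
  class(tl) <- c("trial_timeline", "data.frame")
  tl
}

#' Write a timeline as a BIDS-events-like TSV
#'
#' @param timeline a `trial_timeline` (or compatible data.frame).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_events_tsv <- function(timeline, path) {
  df <- as.data.frame(timeline)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' Read a timeline written by [write_events_tsv()]
#'
#' @param path TSV file path.
#' @return a data.frame with the events-table columns.
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          na.strings = "n/a", stringsAsFactors = FALSE)
  class(df) <- c("trial_timeline", "data.frame")
  df
}
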