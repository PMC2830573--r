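# Shared fixtures, trained once per test run and memoised.
.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

mini_fixture <- function() memo("mini_fx", generate_fixture("mini"))

mini_network <- function() memo("mini_net", bilex_network(mini_fixture()))

# networks after phases i and ii on the mini profile
mini_phase1 <- function() memo("mini_p1", train_phase1(mini_network()))
mini_phase2 <- function() memo("mini_p2", train_phase2(mini_phase1()))

# full mini curriculum with proficiency checkpoints
mini_checkpoints <- function() memo("mini_ck", {
  ck <- list(untrained = mini_phase2(), weak = NULL, strong = NULL)
  net <- ck$untrained
  hist <- data.frame(epoch = integer(), ratio = numeric())
  for (ep in 1:40) {
    net <- train_phase3(net, epochs = 1)
    r <- l2_weight_ratio(net)
    hist <- rbind(hist, data.frame(epoch = ep, ratio = r))
    if (is.null(ck$weak) && r >= net$train$weak_ratio) ck$weak <- net
    if (r >= net$train$strong_ratio) { ck$strong <- net; break }
  }
  ck$history <- hist
  ck
})

# reference-scale curriculum + scenario grid (built once; used by the
# acceptance suite)
paper_checkpoints <- function() memo("paper_ck",
  train_curriculum(bilex_network(generate_fixture("paper2010"))))

paper_matrix <- function() memo("paper_mx",
  scenario_matrix(paper_checkpoints(), duration_ms = 600,
                  keep_scenarios = TRUE))

matrix_row <- function(m, checkpoint, stimulus, bias, word) {
  r <- m[m$checkpoint == checkpoint & m$stimulus == stimulus &
         m$bias == bias & m$word == word, ]
  stopifnot(nrow(r) == 1)
  r
}
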