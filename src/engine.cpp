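#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Declarative memory for one session: 2K instances over K colours.
// Instances 0..K-1 are word-reading traces (word = colour i+1, colour slot
// neutral = 0); instances K..2K-1 are colour-naming traces (colour = i+1,
// word slot neutral).  Baseline events are laid down at ticks 1..2K and the
// event clock starts at 2K+1.  Time is event-count time; seconds appear
// only in latencies.

struct SheetSpec {
  int kind;                // 0 = word, 1 = color, 2 = color_word
  std::vector<int> word;   // word id per item (0 = neutral token)
  std::vector<int> ink;    // ink id per item (0 = neutral ink)
};

static double base_level(const std::vector<int> &ev, int now, double d) {
  double s = 0.0;
  for (size_t i = 0; i < ev.size(); ++i)
    s += std::pow((double)(now - ev[i]), -d);
  return std::log(s);
}

// [[Rcpp::export]]
List cpp_run_session(List sheets, double F, double f, double d, double s,
                     double P, double tau, bool has_tau, double t0,
                     double budget, double skip_penalty, int n_colors) {
  const int K = n_colors, M = 2 * K;
  std::vector<std::vector<int>> events(M);
  std::vector<int> inst_color(M), inst_word(M);
  for (int i = 0; i < K; ++i) {       // word-reading instances
    inst_color[i] = 0; inst_word[i] = i + 1;
    events[i].push_back(i + 1);
  }
  for (int i = 0; i < K; ++i) {       // colour-naming instances
    inst_color[K + i] = i + 1; inst_word[K + i] = 0;
    events[K + i].push_back(K + i + 1);
  }
  int now = M + 1;

  const int n_sheets = sheets.size();
  IntegerVector completed(n_sheets), attempts(n_sheets), failures(n_sheets);
  List latencies(n_sheets);
  NumericVector b(M), act(M);

  RNGScope rng;
  for (int sh = 0; sh < n_sheets; ++sh) {
    List spec = sheets[sh];
    int kind = as<int>(spec["kind"]);
    IntegerVector word = spec["word"];
    IntegerVector ink = spec["ink"];
    int n_items = word.size();
    std::vector<double> lat;
    lat.reserve(n_items);
    double cum = 0.0;
    int done = 0, att = 0, fail = 0;

    for (int it = 0; it < n_items; ++it) {
      ++att;
      for (int i = 0; i < M; ++i) {
        b[i] = base_level(events[i], now, d);
        double pen = 0.0;
        if (kind == 0) {                       // name the word
          if (inst_word[i] != word[it]) pen -= P;
        } else if (kind == 1) {                // name the ink
          if (inst_color[i] != ink[it]) pen -= P;
        } else {                               // ink requested, word as context
          if (inst_color[i] != ink[it]) pen -= P;
          if (inst_word[i] != word[it]) pen -= P;
        }
        double eps = 0.0;
        if (s > 0.0) {
          double u = R::runif(0.0, 1.0);
          eps = s * std::log((1.0 - u) / u);
        }
        act[i] = b[i] + pen + eps;
      }
      int win = 0;
      for (int i = 1; i < M; ++i) if (act[i] > act[win]) win = i;

      if (has_tau && act[win] < tau) {         // retrieval failure: skip item
        ++fail;
        lat.push_back(skip_penalty);
        cum += skip_penalty;
        if (cum > budget) break;
        continue;
      }
      double rt = F * std::exp(-f * act[win]) + t0;
      lat.push_back(rt);
      // every attempt leaves a trace: commit before the budget check so the
      // pure-R engine (which retrieves, then checks) stays draw-identical
      events[win].push_back(now);
      ++now;
      if (cum + rt <= budget) {
        cum += rt;
        ++done;
      } else {
        break;
      }
    }
    completed[sh] = done;
    attempts[sh] = att;
    failures[sh] = fail;
    latencies[sh] = NumericVector(lat.begin(), lat.end());
  }

  return List::create(_["completed"] = completed,
                      _["attempts"] = attempts,
                      _["failures"] = failures,
                      _["latencies"] = latencies);
}
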