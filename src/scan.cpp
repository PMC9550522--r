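#include <Rcpp.h>
using namespace Rcpp;

// Sliding-window polyXY test over one protein sequence.
//
// A window is positive iff it contains exactly two distinct residue types,
// each occurring at least twice, and every character is one of the 20
// standard amino acids. Ambiguity codes (B, J, O, U, X, Z), stops ('*') and
// gaps disqualify any window touching them.
//
// Returns an integer matrix with one row per positive window:
//   col 0: 1-based window start
//   col 1, col 2: the two residue types as uppercase ASCII codes, col1 < col2
//
// Counts are maintained incrementally so the scan is O(L) in sequence length.

static const bool STANDARD[26] = {
  /*A*/ true,  /*B*/ false, /*C*/ true,  /*D*/ true,  /*E*/ true,
  /*F*/ true,  /*G*/ true,  /*H*/ true,  /*I*/ true,  /*J*/ false,
  /*K*/ true,  /*L*/ true,  /*M*/ true,  /*N*/ true,  /*O*/ false,
  /*P*/ true,  /*Q*/ true,  /*R*/ true,  /*S*/ true,  /*T*/ true,
  /*U*/ false, /*V*/ true,  /*W*/ true,  /*X*/ false, /*Y*/ true,
  /*Z*/ false
};

// [[Rcpp::export(name = ".scanWindowsC")]]
IntegerMatrix scanWindowsC(std::string seq, int window) {
  const int L = (int) seq.size();
  const int n = L - window + 1;
  if (n < 1) return IntegerMatrix(0, 3);

  int counts[27];            // slot 26 pools every non-standard character
  for (int i = 0; i < 27; ++i) counts[i] = 0;

  std::vector<int> code(L);
  for (int i = 0; i < L; ++i) {
    char c = seq[i];
    int k = (c >= 'A' && c <= 'Z') ? c - 'A' : 26;
    if (k < 26 && !STANDARD[k]) k = 26;
    code[i] = k;
  }

  std::vector<int> starts;
  std::vector<int> aa1, aa2;

  int nTypes = 0;            // distinct standard residues in window
  int nSingle = 0;           // standard residues occurring exactly once
  int nBad = 0;              // non-standard characters in window

  for (int i = 0; i < L; ++i) {
    int k = code[i];
    if (k == 26) {
      ++nBad;
    } else {
      int c = ++counts[k];
      if (c == 1) { ++nTypes; ++nSingle; }
      else if (c == 2) { --nSingle; }
    }
    if (i >= window) {       // drop the residue leaving the window
      int kd = code[i - window];
      if (kd == 26) {
        --nBad;
      } else {
        int c = --counts[kd];
        if (c == 0) { --nTypes; --nSingle; }
        else if (c == 1) { ++nSingle; }
      }
    }
    if (i >= window - 1 && nBad == 0 && nTypes == 2 && nSingle == 0) {
      int a = -1, b = -1;
      for (int k2 = 0; k2 < 26; ++k2) {
        if (counts[k2] > 0) { if (a < 0) a = k2; else { b = k2; break; } }
      }
      starts.push_back(i - window + 2);   // 1-based start
      aa1.push_back('A' + a);
      aa2.push_back('A' + b);
    }
  }

  const int m = (int) starts.size();
  IntegerMatrix out(m, 3);
  for (int r = 0; r < m; ++r) {
    out(r, 0) = starts[r];
    out(r, 1) = aa1[r];
    out(r, 2) = aa2[r];
  }
  return out;
}
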