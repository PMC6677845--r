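# Sobol' direction-number initialisation: primitive polynomials and initial

# m-values for the first 160 dimensions, from the Joe & Kuo (2008) table of

# direction numbers (new-joe-kuo-6, BSD-licensed data). Row j parameterises

# dimension j; unused trailing m-values are zero.

.sobol_poly <- c(
  1, 3, 7, 11, 13, 19, 25, 37, 41, 47, 55, 59, 61, 67, 91, 97, 103, 109, 115, 131,
  137, 143, 145, 157, 167, 171, 185, 191, 193, 203, 211, 213, 229, 239, 241, 247, 253, 285, 299, 301,
  333, 351, 355, 357, 361, 369, 391, 397, 425, 451, 463, 487, 501, 529, 539, 545, 557, 563, 601, 607,
  617, 623, 631, 637, 647, 661, 675, 677, 687, 695, 701, 719, 721, 731, 757, 761, 787, 789, 799, 803,
  817, 827, 847, 859, 865, 875, 877, 883, 895, 901, 911, 949, 953, 967, 971, 973, 981, 985, 995, 1001,
  1019, 1033, 1051, 1063, 1069, 1125, 1135, 1153, 1163, 1221, 1239, 1255, 1267, 1279, 1293, 1305, 1315, 1329, 1341, 1347,
  1367, 1387, 1413, 1423, 1431, 1441, 1479, 1509, 1527, 1531, 1555, 1557, 1573, 1591, 1603, 1615, 1627, 1657, 1663, 1673,
  1717, 1729, 1747, 1759, 1789, 1815, 1821, 1825, 1849, 1863, 1869, 1877, 1881, 1891, 1917, 1933, 1939, 1969, 2011, 2035
)

.sobol_vinit <- matrix(c(
  1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
  0, 0, 3, 3, 1, 1, 3, 1, 1, 1, 1, 1, 3, 3, 1, 3, 1, 3, 1, 3,
  3, 1, 3, 3, 3, 1, 3, 1, 3, 1, 3, 3, 3, 1, 1, 1, 3, 3, 3, 3,
  3, 1, 3, 3, 1, 3, 3, 3, 1, 1, 3, 3, 1, 3, 3, 1, 3, 1, 1, 1,
  3, 1, 1, 1, 1, 1, 1, 1, 3, 1, 3, 1, 1, 1, 1, 1, 3, 3, 3, 1,
  1, 1, 3, 3, 1, 1, 1, 3, 3, 1, 3, 1, 3, 3, 1, 3, 1, 3, 3, 1,
  3, 3, 1, 3, 1, 3, 3, 1, 1, 3, 3, 1, 3, 1, 3, 3, 1, 3, 1, 1,
  3, 3, 1, 3, 1, 3, 3, 3, 3, 1, 1, 3, 3, 1, 3, 1, 1, 1, 1, 3,
  3, 1, 1, 3, 3, 1, 3, 1, 3, 1, 3, 1, 3, 1, 3, 3, 3, 3, 1, 1,
  0, 0, 0, 1, 1, 3, 5, 5, 5, 7, 5, 1, 5, 3, 1, 1, 1, 1, 5, 7,
  7, 3, 5, 1, 1, 5, 5, 7, 7, 3, 5, 7, 1, 5, 7, 7, 3, 1, 5, 1,
  1, 7, 7, 1, 5, 7, 3, 7, 3, 1, 7, 1, 3, 5, 3, 1, 1, 1, 5, 5,
  7, 1, 5, 3, 1, 7, 5, 7, 5, 3, 3, 3, 5, 5, 1, 3, 1, 1, 5, 5,
  3, 1, 3, 5, 7, 3, 7, 7, 1, 1, 1, 7, 3, 3, 3, 7, 7, 3, 5, 5,
  3, 1, 7, 1, 3, 7, 5, 5, 7, 1, 7, 5, 3, 7, 1, 5, 3, 7, 1, 5,
  7, 7, 3, 3, 5, 5, 7, 3, 7, 3, 3, 1, 1, 7, 7, 5, 3, 3, 3, 1,
  3, 1, 7, 5, 3, 3, 7, 3, 3, 3, 7, 1, 1, 5, 3, 5, 1, 3, 7, 7,
  0, 0, 0, 0, 0, 3, 13, 5, 5, 11, 1, 3, 5, 9, 15, 13, 15, 15, 5, 11,
  13, 13, 9, 13, 5, 11, 3, 13, 5, 9, 13, 3, 3, 5, 7, 9, 5, 15, 15, 11,
  11, 15, 3, 1, 9, 11, 3, 11, 1, 3, 7, 5, 5, 5, 11, 5, 5, 11, 11, 15,
  7, 3, 13, 13, 11, 11, 5, 13, 1, 13, 1, 3, 7, 11, 5, 15, 11, 1, 3, 3,
  5, 11, 5, 9, 1, 5, 15, 3, 15, 1, 15, 3, 3, 7, 9, 15, 1, 13, 3, 5,
  7, 15, 5, 7, 13, 13, 5, 3, 9, 7, 1, 11, 13, 7, 9, 13, 3, 1, 7, 9,
  7, 1, 11, 5, 3, 9, 7, 7, 7, 13, 9, 9, 13, 3, 13, 5, 7, 1, 15, 7,
  3, 13, 7, 1, 7, 15, 1, 7, 13, 5, 7, 9, 15, 15, 5, 13, 11, 11, 9, 13,
  0, 0, 0, 0, 0, 0, 0, 17, 5, 19, 1, 11, 31, 7, 21, 27, 7, 13, 19, 23,
  13, 7, 1, 9, 27, 19, 3, 1, 13, 25, 23, 13, 5, 23, 1, 13, 3, 31, 31, 11,
  27, 21, 25, 19, 19, 1, 15, 15, 11, 23, 17, 27, 11, 29, 3, 17, 25, 11, 9, 19,
  31, 23, 31, 25, 21, 11, 17, 23, 9, 31, 5, 1, 23, 17, 1, 1, 7, 15, 27, 1,
  5, 7, 27, 11, 23, 23, 7, 9, 19, 1, 15, 19, 5, 9, 11, 25, 9, 19, 23, 11,
  29, 5, 5, 9, 9, 19, 19, 31, 13, 21, 3, 1, 9, 15, 25, 31, 31, 13, 21, 17,
  13, 23, 17, 11, 15, 1, 5, 5, 17, 11, 29, 1, 21, 17, 11, 13, 27, 23, 25, 7,
  25, 25, 27, 23, 11, 13, 5, 1, 5, 13, 1, 1, 23, 29, 19, 9, 27, 19, 21, 15,
  0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 49, 21, 49, 5, 25, 61, 15,
  15, 35, 25, 35, 61, 41, 13, 19, 19, 29, 1, 59, 53, 33, 61, 61, 55, 13, 59, 11,
  43, 11, 31, 11, 21, 33, 9, 39, 31, 43, 17, 63, 43, 17, 1, 39, 15, 17, 29, 45,
  19, 15, 15, 47, 53, 7, 13, 7, 43, 13, 63, 19, 31, 53, 13, 57, 43, 27, 61, 3,
  57, 11, 59, 49, 45, 5, 11, 13, 39, 33, 43, 27, 35, 27, 17, 57, 55, 27, 43, 5,
  37, 5, 39, 7, 47, 13, 59, 63, 39, 17, 31, 61, 61, 29, 9, 47, 57, 57, 13, 51,
  45, 57, 47, 21, 55, 23, 49, 41, 23, 39, 3, 29, 39, 63, 33, 57, 63, 29, 55, 19,
  55, 17, 49, 5, 61, 7, 31, 43, 1, 19, 19, 25, 57, 21, 45, 61, 25, 7, 39, 41,
  0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 103,
  69, 63, 53, 107, 31, 61, 69, 1, 59, 41, 55, 17, 69, 13, 123, 49, 33, 49, 63, 77,
  71, 81, 65, 3, 29, 89, 79, 119, 97, 57, 37, 123, 53, 47, 109, 23, 31, 63, 97, 41,
  83, 111, 55, 39, 125, 57, 81, 65, 3, 13, 89, 123, 37, 117, 13, 115, 81, 63, 105, 57,
  15, 105, 121, 51, 125, 105, 67, 31, 39, 73, 29, 85, 23, 39, 13, 33, 73, 23, 3, 45,
  33, 37, 63, 87, 7, 9, 7, 15, 3, 97, 71, 83, 19, 63, 71, 101, 125, 67, 105, 45,
  91, 67, 93, 43, 101, 29, 29, 127, 117, 21, 95, 117, 125, 115, 101, 63, 93, 1, 9, 51,
  17, 65, 99, 43, 39, 29, 47, 9, 119, 3, 91, 109, 59, 39, 61, 107, 85, 115, 123, 47,
  0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
  0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 245, 97, 249,
  9, 45, 79, 205, 157, 185, 71, 27, 225, 177, 71, 213, 133, 173, 9, 5, 103, 105, 231, 7,
  137, 223, 25, 87, 249, 79, 3, 251, 149, 255, 91, 127, 243, 183, 209, 7, 207, 255, 171, 249,
  13, 141, 101, 59, 71, 109, 121, 27, 89, 145, 13, 131, 195, 59, 241, 189, 83, 113, 253, 117,
  123, 227, 255, 249, 225, 67, 41, 43, 47, 19, 111, 119, 97, 95, 57, 57, 173, 157, 89, 119,
  9, 141, 107, 51, 67, 47, 155, 61, 67, 207, 47, 21, 211, 89, 107, 135, 47, 191, 101, 251,
  75, 45, 161, 41, 87, 7, 157, 147, 211, 243, 249, 197, 135, 253, 151, 141, 105, 223, 21, 243,
  0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
  0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
  0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 479, 69, 343, 499, 183, 363, 383,
  221, 83, 161, 257, 293, 323, 131, 475, 11, 487, 127, 237, 289, 491, 345, 33, 175, 49, 305, 149,
  159, 225, 271, 115, 419, 75, 453, 449, 15, 379, 483, 431, 349, 297, 157, 213, 217, 249, 479, 217,
  147, 223, 135, 217, 363, 9, 319, 207, 497, 415, 165, 203, 47, 417, 213, 39, 365, 451, 429, 157,
  129, 151, 375, 169, 455, 345, 323, 261, 129, 123, 231, 441, 439, 49, 63, 437, 417, 49, 219, 393,
  337, 479, 213, 251, 383, 505, 445, 115, 455, 75, 357, 279, 191, 383, 199, 141, 309, 349, 275, 303,
  0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
  0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
  0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
  0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
  0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
  0, 459, 487, 599, 247, 737, 677, 789, 169, 905, 127, 847, 35, 469, 385, 341, 551, 707, 965, 141,
  741, 571, 157, 915, 625, 595, 589, 717, 1009, 305, 73, 259, 723, 773, 73, 177, 483, 23, 607, 307,
  3, 413, 727, 857, 835, 923, 501, 605, 1001, 843, 589, 411, 75, 349, 981, 1, 979, 43, 927, 437
), nrow = 160, ncol = 10)

.sobol_max_dim <- 160L
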