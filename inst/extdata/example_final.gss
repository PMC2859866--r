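# Example final GSS set: eight simulated mitogenome structure sequences
# (77 synteny anchors each, duplicates resolved; see ?read_gss)
G1	53 54 15 16 12 13 -50a -49a -48 -47a -46 -64 56b 57b -50b 68 -44b -44a -42 -41b -41a -40b -40a 61 62 63a 63b 58 17 18 19 20 21 22 23 -24 25 26 27 28 29 30 -39 10 11 14 55 56a 57a -34 35 36 37 38 -9b -9a -8 -59 -33 -32 -31 -60 69 1 2 3 4 5a 5b 6a 6b 7 65 66 67 -49b -47b
G2	-11 -10 39 40a 40b 41a 41b 42 44a 44b -68 -67 -66 -65 -7 -6b -6a -5b -5a -4 -3 -2 -1 -69 60 61 62 63a 47b 49b 50b -57b -56b 63b 64 46 47a 48 49a 50a -58 53 54 15 16 17 18 19 20 36 37 38 -9b -9a -8 -59 -33 -32 -31 -30 -29 -28 -27 -26 -25 24 -23 -22 -21 -35 34 -57a -56a -55 -14 -13 -12
G5	-55 -14 -13 -12 -11 60 61 62 63a 47b 49b 50b -57b -56b 63b 64 56a -19 -18 -17 -16 -15 -54 -53 58 34 -57a 20 -21 22 23 -24 25 26 27 28 -33 -32 -31 -30 -29 59 -68 -67 -66 -65 -7 -6b -6a -5b -5a -4 -3 -2 -1 -69 46 47a 48 49a 50a 35 36 37 38 -9b -9a -8 -44b -44a -42 -41b -41a -40b -40a -39 10
G6	-9b -9a 53 54 -24 -23 -22 -21 -20 -19 -58 -57b -57a -56b -56a -55 -14 16 17 -41b -41a -37 -36 -35 -34 -33 -32 -31 -59 -18 42 44a 44b 46 47a 47b 48 49a 49b 50a 50b -8 11 12 13 -15 25 26 27 28 29 30 -68 -67 -66 -65 -7 -6b -6a -5b -5a -4 -3 -2 -1 -69 60 61 62 63a 63b 64 -10 39 40a 40b 38
G3	-46 -44b -44a -42 -41b -41a -37 -36 -35 -34 -33 -32 -31 -59 -18 -17 -16 14 55 47a 47b 48 49a 49b 50a 50b 56a 56b 38 -9b -9a -8 -58 -57b -57a -40b -40a -39 10 -64 -7 -6b -6a -5b -5a -4 -3 -2 -1 -69 60 61 62 63a 63b 65 66 22 23 24 25 26 27 28 29 30 -68 -67 -21 -20 -19 11 12 13 -15 -54 -53
G4	44a 44b 46 47a 47b 48 49a 49b 50a 50b 53 54 15 -13 -12 -11 8 9a 9b -38 -37 -36 -35 -34 -33 -32 -31 -59 -18 -17 -16 14 55 56a 56b 57a 57b 58 -42 -41a -40b -40a -41b 24 25 26 27 28 29 30 -68 -67 -66 -65 -7 -6b -6a -5b -5a -4 -3 -2 -1 -69 60 61 62 63a 63b 64 -10 39 -23 -22 -21 -20 -19
G8	67 68 69 1 2 3 5a 5b 6a 6b 10 11 12 13 14 15 16 17 18 19 20 21 22 23 24 25 26 27 28 29 30 63a 63b 64 -66 -65 7 -49b -49a -48 -47b -47a -46 -44b -44a -42 -41b -41a -40b -40a -39 -38 -37 -36 -35 -34 -33 -32 -31 -62 -61 -60 -59 -58 -57b -57a -56b -56a -55 -54 -53 -50b -50a 8 9a 9b 4
G7	15 17 16 -36 -37 -35 -34 -33 -32 -31 -62 -61 -60 -59 -6a -5b -4 -9b -9a -8 50a 50b 18 19 -20 21 -25 -24 -23 -22 26 27 28 29 30 63a 63b 64 65 66 67 68 69 1 2 46 47a 47b 48 49a 49b -7 -6b -5a -3 -44a -42 -41a -40b -44b -41b -40a -39 -38 53 54 55 56a 56b 57a 57b 58 10 11 -12 13 14
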