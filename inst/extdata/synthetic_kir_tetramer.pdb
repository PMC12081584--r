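ATOM      1  CA  ALA A 164       4.198  12.290  -0.072  1.00  0.00
ATOM      2  CA  ALA A 165       2.748   8.739   1.461  1.00  0.00
ATOM      3  CA  ALA A 166      11.433   7.012   2.722  1.00  0.00
ATOM      4  CA  ALA A 167       5.406  12.043   4.784  1.00  0.00
ATOM      5  CA  ALA A 168       5.228   7.178   5.959  1.00  0.00
ATOM      6  CA  ALA A 169       7.640   7.967   7.775  1.00  0.00
ATOM      7  CA  ALA A 170       5.223   9.014   9.233  1.00  0.00
ATOM      8  CA  ALA A 171      12.052   4.863  10.584  1.00  0.00
ATOM      9  CA  ALA A 172       6.155   8.755  12.283  1.00  0.00
ATOM     10  CA  GLN A 173       7.755   7.755  13.500  1.00  0.00
ATOM     11  CA  ALA A 174       8.985   8.186  14.900  1.00  0.00
ATOM     12  CA  ALA A 175       6.485  10.712  16.408  1.00  0.00
ATOM     13  CA  ALA A 176       3.148   9.920  17.939  1.00  0.00
ATOM     14  CA  ALA A 177      10.342   5.872  19.671  1.00  0.00
ATOM     15  CA  ALA A 178       6.245   5.747  20.723  1.00  0.00
ATOM     16  CA  ALA A 179       3.750  12.062  22.649  1.00  0.00
ATOM     17  CA  ALA A 180       2.181   8.220  24.106  1.00  0.00
ATOM     18  CA  ALA A 181       8.881   3.390  25.303  1.00  0.00
ATOM     19  CA  ALA A 182       9.442   8.936  26.857  1.00  0.00
ATOM     20  CA  ALA A 183       7.592   8.673  28.509  1.00  0.00
ATOM     21  CA  ALA B 164     -12.290   4.198  -0.072  1.00  0.00
ATOM     22  CA  ALA B 165      -8.739   2.748   1.461  1.00  0.00
ATOM     23  CA  ALA B 166      -7.012  11.433   2.722  1.00  0.00
ATOM     24  CA  ALA B 167     -12.043   5.406   4.784  1.00  0.00
ATOM     25  CA  ALA B 168      -7.178   5.228   5.959  1.00  0.00
ATOM     26  CA  ALA B 169      -7.967   7.640   7.775  1.00  0.00
ATOM     27  CA  ALA B 170      -9.014   5.223   9.233  1.00  0.00
ATOM     28  CA  ALA B 171      -4.863  12.052  10.584  1.00  0.00
ATOM     29  CA  ALA B 172      -8.755   6.155  12.283  1.00  0.00
ATOM     30  CA  GLN B 173      -7.755   7.755  13.500  1.00  0.00
ATOM     31  CA  ALA B 174      -8.186   8.985  14.900  1.00  0.00
ATOM     32  CA  ALA B 175     -10.712   6.485  16.408  1.00  0.00
ATOM     33  CA  ALA B 176      -9.920   3.148  17.939  1.00  0.00
ATOM     34  CA  ALA B 177      -5.872  10.342  19.671  1.00  0.00
ATOM     35  CA  ALA B 178      -5.747   6.245  20.723  1.00  0.00
ATOM     36  CA  ALA B 179     -12.062   3.750  22.649  1.00  0.00
ATOM     37  CA  ALA B 180      -8.220   2.181  24.106  1.00  0.00
ATOM     38  CA  ALA B 181      -3.390   8.881  25.303  1.00  0.00
ATOM     39  CA  ALA B 182      -8.936   9.442  26.857  1.00  0.00
ATOM     40  CA  ALA B 183      -8.673   7.592  28.509  1.00  0.00
ATOM     41  CA  ALA C 164      -4.198 -12.290  -0.072  1.00  0.00
ATOM     42  CA  ALA C 165      -2.748  -8.739   1.461  1.00  0.00
ATOM     43  CA  ALA C 166     -11.433  -7.012   2.722  1.00  0.00
ATOM     44  CA  ALA C 167      -5.406 -12.043   4.784  1.00  0.00
ATOM     45  CA  ALA C 168      -5.228  -7.178   5.959  1.00  0.00
ATOM     46  CA  ALA C 169      -7.640  -7.967   7.775  1.00  0.00
ATOM     47  CA  ALA C 170      -5.223  -9.014   9.233  1.00  0.00
ATOM     48  CA  ALA C 171     -12.052  -4.863  10.584  1.00  0.00
ATOM     49  CA  ALA C 172      -6.155  -8.755  12.283  1.00  0.00
ATOM     50  CA  GLN C 173      -7.755  -7.755  13.500  1.00  0.00
ATOM     51  CA  ALA C 174      -8.985  -8.186  14.900  1.00  0.00
ATOM     52  CA  ALA C 175      -6.485 -10.712  16.408  1.00  0.00
ATOM     53  CA  ALA C 176      -3.148  -9.920  17.939  1.00  0.00
ATOM     54  CA  ALA C 177     -10.342  -5.872  19.671  1.00  0.00
ATOM     55  CA  ALA C 178      -6.245  -5.747  20.723  1.00  0.00
ATOM     56  CA  ALA C 179      -3.750 -12.062  22.649  1.00  0.00
ATOM     57  CA  ALA C 180      -2.181  -8.220  24.106  1.00  0.00
ATOM     58  CA  ALA C 181      -8.881  -3.390  25.303  1.00  0.00
ATOM     59  CA  ALA C 182      -9.442  -8.936  26.857  1.00  0.00
ATOM     60  CA  ALA C 183      -7.592  -8.673  28.509  1.00  0.00
ATOM     61  CA  ALA D 164      12.290  -4.198  -0.072  1.00  0.00
ATOM     62  CA  ALA D 165       8.739  -2.748   1.461  1.00  0.00
ATOM     63  CA  ALA D 166       7.012 -11.433   2.722  1.00  0.00
ATOM     64  CA  ALA D 167      12.043  -5.406   4.784  1.00  0.00
ATOM     65  CA  ALA D 168       7.178  -5.228   5.959  1.00  0.00
ATOM     66  CA  ALA D 169       7.967  -7.640   7.775  1.00  0.00
ATOM     67  CA  ALA D 170       9.014  -5.223   9.233  1.00  0.00
ATOM     68  CA  ALA D 171       4.863 -12.052  10.584  1.00  0.00
ATOM     69  CA  ALA D 172       8.755  -6.155  12.283  1.00  0.00
ATOM     70  CA  GLN D 173       7.755  -7.755  13.500  1.00  0.00
ATOM     71  CA  ALA D 174       8.186  -8.985  14.900  1.00  0.00
ATOM     72  CA  ALA D 175      10.712  -6.485  16.408  1.00  0.00
ATOM     73  CA  ALA D 176       9.920  -3.148  17.939  1.00  0.00
ATOM     74  CA  ALA D 177       5.872 -10.342  19.671  1.00  0.00
ATOM     75  CA  ALA D 178       5.747  -6.245  20.723  1.00  0.00
ATOM     76  CA  ALA D 179      12.062  -3.750  22.649  1.00  0.00
ATOM     77  CA  ALA D 180       8.220  -2.181  24.106  1.00  0.00
ATOM     78  CA  ALA D 181       3.390  -8.881  25.303  1.00  0.00
ATOM     79  CA  ALA D 182       8.936  -9.442  26.857  1.00  0.00
ATOM     80  CA  ALA D 183       8.673  -7.592  28.509  1.00  0.00
END
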