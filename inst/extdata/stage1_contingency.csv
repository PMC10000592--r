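classifier,actual,predicted,count
mlp,1,1,128
mlp,1,2,1
mlp,1,3,8
mlp,2,1,0
mlp,2,2,151
mlp,2,3,3
mlp,3,1,9
mlp,3,2,8
mlp,3,3,91
rf,1,1,131
rf,1,2,0
rf,1,3,6
rf,2,1,0
rf,2,2,151
rf,2,3,3
rf,3,1,3
rf,3,2,1
rf,3,3,104
svm,1,1,132
svm,1,2,0
svm,1,3,4
svm,2,1,1
svm,2,2,152
svm,2,3,3
svm,3,1,4
svm,3,2,0
svm,3,3,103
bagging,1,1,129
bagging,1,2,0
bagging,1,3,6
bagging,2,1,2
bagging,2,2,145
bagging,2,3,7
bagging,3,1,4
bagging,3,2,6
bagging,3,3,100
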