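task,approach,feature_set,classifier,accuracy
binary,raw,all,knn,56.7
binary,raw,all,linear_svm,73.3
binary,raw,all,decision_tree,53.3
binary,raw,all,ensemble_bagged_tree,60
multiclass,raw,all,knn,46
multiclass,raw,all,linear_svm,35.5
multiclass,raw,all,decision_tree,40
multiclass,raw,all,ensemble_bagged_tree,45.5
binary,bands,all,knn,36.7
binary,bands,all,linear_svm,66.7
binary,bands,all,decision_tree,30
binary,bands,all,ensemble_bagged_tree,36.7
multiclass,bands,all,knn,34.5
multiclass,bands,all,linear_svm,45
multiclass,bands,all,decision_tree,43.5
multiclass,bands,all,ensemble_bagged_tree,42.5
binary,vmd,all,knn,60
binary,vmd,all,linear_svm,80
binary,vmd,all,decision_tree,63.3
binary,vmd,all,ensemble_bagged_tree,83.3
multiclass,vmd,all,knn,46
multiclass,vmd,all,linear_svm,57
multiclass,vmd,all,decision_tree,73.5
multiclass,vmd,all,ensemble_bagged_tree,76
binary,raw,selected,knn,56.7
binary,raw,selected,linear_svm,50
binary,raw,selected,decision_tree,43.3
binary,raw,selected,ensemble_bagged_tree,53.3
multiclass,raw,selected,knn,44
multiclass,raw,selected,linear_svm,32.5
multiclass,raw,selected,decision_tree,55
multiclass,raw,selected,ensemble_bagged_tree,50
binary,bands,selected,knn,70
binary,bands,selected,linear_svm,46.7
binary,bands,selected,decision_tree,56.7
binary,bands,selected,ensemble_bagged_tree,76.7
multiclass,bands,selected,knn,42
multiclass,bands,selected,linear_svm,49
multiclass,bands,selected,decision_tree,52
multiclass,bands,selected,ensemble_bagged_tree,53.5
binary,vmd,selected,knn,73.3
binary,vmd,selected,linear_svm,80
binary,vmd,selected,decision_tree,66.7
binary,vmd,selected,ensemble_bagged_tree,86.7
multiclass,vmd,selected,knn,61
multiclass,vmd,selected,linear_svm,70.5
multiclass,vmd,selected,decision_tree,57.5
multiclass,vmd,selected,ensemble_bagged_tree,80.5
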